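<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_branched" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="C_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="D_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="lb_rev" value="-1000" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="G_g4" fbc:label="g4"/>
      <fbc:geneProduct fbc:id="G_g5" fbc:label="g5"/>
      <fbc:geneProduct fbc:id="G_g6" fbc:label="g6"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: exchange</p></body></notes>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_AB1" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: upper pathway</p></body></notes>
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_g1" fbc:label="g1"/>
            <fbc:geneProductRef fbc:geneProduct="G_g2" fbc:label="g2"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_AB2" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: upper pathway</p></body></notes>
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g3" fbc:label="g3"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_BC" reversible="true" fast="false" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_default">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: lower pathway</p></body></notes>
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_g4" fbc:label="g4"/>
            <fbc:geneProductRef fbc:geneProduct="G_g5" fbc:label="g5"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_CD" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: lower pathway</p></body></notes>
        <listOfReactants>
          <speciesReference species="C_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="D_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g6" fbc:label="g6"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_D" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: exchange</p></body></notes>
        <listOfReactants>
          <speciesReference species="D_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
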