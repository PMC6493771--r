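test_that("COBRA JSON fixture loads with expected structure", {
  m <- load_model(extdata_path("toy_model.json"))
  expect_s3_class(m, "minea_model")
  expect_equal(nrow(m$reactions), 6)
  expect_equal(nrow(m$metabolites), 4)
  expect_setequal(m$genes, paste0("g", 1:6))
  expect_equal(m$reactions$lb[m$reactions$id == "R_BC"], -1000)
  expect_equal(unname(as.matrix(m$stoich)["B_c", "R_AB1"]), 1)
})

test_that("SBML (fbc) loader agrees with the JSON loader on the same model", {
  mj <- load_model(extdata_path("toy_model.json"))
  mx <- load_model(extdata_path("toy_model.xml"))
  expect_identical(mj$reactions$id, mx$reactions$id)
  expect_identical(mj$reactions$lb, mx$reactions$lb)
  expect_identical(mj$reactions$ub, mx$reactions$ub)
  expect_identical(sort(mj$genes), sort(mx$genes))
  for (id in mj$reactions$id) {
    expect_setequal(genes_of(mj, id), genes_of(mx, id))
  }
  expect_identical(as.matrix(mj$stoich), as.matrix(mx$stoich))
})

test_that("load -> write -> load round-trips structurally", {
  m <- load_model(extdata_path("toy_model.json"))
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- load_model(path)
  expect_identical(m$reactions$id, m2$reactions$id)
  expect_identical(m$reactions$lb, m2$reactions$lb)
  expect_identical(m$reactions$ub, m2$reactions$ub)
  expect_identical(as.matrix(m$stoich), as.matrix(m2$stoich))
  for (id in m$reactions$id) {
    expect_setequal(genes_of(m, id), genes_of(m2, id))
  }
})

test_that("malformed models are rejected with informative errors", {
  bad <- tempfile(fileext = ".json")
  writeLines('{"metabolites": [{"id": "A_c"}], "reactions": [
    {"id": "R1", "metabolites": {}, "lower_bound": 0, "upper_bound": 10}]}',
    bad)
  expect_error(load_model(bad), "R1.*no stoichiometry")
  writeLines("{not json", bad)
  expect_error(load_model(bad), "malformed")
  expect_error(
    minea_model("dup",
                metabolites = data.frame(id = "A", compartment = "c"),
                reactions = data.frame(id = c("R1", "R1"), lb = 0, ub = 1),
                stoich = data.frame(metabolite = "A",
                                    reaction = c("R1", "R1"),
                                    coefficient = c(1, 1))),
    "duplicate reaction ids")
})

test_that("GPR parsing handles both dialects and collects leaves", {
  expect_setequal(gpr_genes(parse_gpr("(g1 and g2) or g3")),
                  c("g1", "g2", "g3"))
  expect_setequal(gpr_genes(parse_gpr("(g1 & g2) | g3")),
                  c("g1", "g2", "g3"))
  expect_setequal(gpr_genes(parse_gpr("(G1 AND g2) OR g3")),
                  c("G1", "g2", "g3"))
  expect_identical(gpr_genes(parse_gpr("")), character(0))
  expect_null(parse_gpr("  "))
  # set semantics: repeated leaves are deduplicated
  expect_setequal(gpr_genes(parse_gpr("g1 or (g1 and g2)")), c("g1", "g2"))
  expect_error(parse_gpr("g1 and (g2"), "malformed GPR")
  expect_error(parse_gpr("and g1"), "malformed GPR")
})

test_that("genes_of is invariant under leaf-preserving GPR rewrites", {
  m <- toy_chain_model()
  expect_setequal(genes_of(m, "R2"), c("g1", "g2"))
  equivalents <- c("g1 or (g1 and g2)", "(g2 and g1) or g1", "g1 | g2 & g1")
  leafsets <- lapply(equivalents, function(s) sort(gpr_genes(parse_gpr(s))))
  expect_true(all(vapply(leafsets, identical, logical(1), leafsets[[1]])))
  expect_identical(genes_of(m, "R1"), character(0))
})

test_that("split_reversible produces the documented forward pairs", {
  m <- toy_chain_model(rev_mid = TRUE)
  sp <- split_reversible(m)
  expect_equal(nrow(sp$reactions), 4)
  expect_true(all(sp$reactions$lb == 0))
  pair <- sp$reactions[sp$reactions$parent_id == "R2", ]
  expect_setequal(pair$id, c("R2_fwd", "R2_rev"))
  expect_equal(pair$ub[pair$id == "R2_fwd"], 1000)
  expect_equal(pair$ub[pair$id == "R2_rev"], 1000)
  expect_equal(unname(as.matrix(sp$stoich)[, "R2_rev"]),
               -unname(as.matrix(sp$stoich)[, "R2_fwd"]))
  # GPR carried to both directions
  expect_setequal(genes_of(sp, "R2_rev"), c("g1", "g2"))
  # irreversible reactions untouched, idempotent overall
  expect_identical(split_reversible(sp)$reactions, sp$reactions)
  m2 <- toy_chain_model(rev_mid = FALSE)
  expect_identical(split_reversible(m2)$reactions$id, m2$reactions$id)
})

test_that("splitting preserves the net feasible flux cone", {
  m <- toy_chain_model(rev_mid = TRUE)
  dm <- add_demand(m, "C")
  sp <- split_reversible(dm$model)
  # max demand flux identical before/after splitting (bottleneck 100)
  post <- fba_max(sp, dm$demand_id)
  expect_equal(post$value, 100)
  net_fwd <- post$fluxes[["R2_fwd"]] - post$fluxes[["R2_rev"]]
  expect_equal(net_fwd, 100)
})

test_that("directionality restrictions silence the forbidden copy", {
  m <- split_reversible(toy_chain_model(rev_mid = TRUE))
  r <- apply_directionality(m, data.frame(reaction_id = "R2",
                                          direction = "forward"))
  expect_equal(r$reactions$ub[r$reactions$id == "R2_rev"], 0)
  expect_equal(r$reactions$ub[r$reactions$id == "R2_fwd"], 1000)
  # empty table is the identity
  expect_identical(apply_directionality(m, data.frame())$reactions,
                   m$reactions)
  expect_error(apply_directionality(m, data.frame(reaction_id = "NOPE",
                                                  direction = "forward")),
               "NOPE")
  # restricting the only route to a target zeroes the achievable yield
  blocked <- apply_directionality(m, data.frame(reaction_id = "R2",
                                                direction = "reverse"))
  dm <- add_demand(blocked, "C")
  expect_equal(compute_max_yield(dm$model, dm$demand_id), 0)
})
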