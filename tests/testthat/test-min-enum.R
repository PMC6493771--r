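test_that("the parallel toy network yields two size-2 minimal networks", {
  m <- toy_parallel_model()
  prep <- prepare_task(split_reversible(m), minea_task("B_SYN", "B"))
  net <- solve_min_network(prep$model, prep$task)
  expect_equal(net$size, 2)
  expect_true(identical(net$active_reactions, c("R1", "R2")) ||
                identical(net$active_reactions, c("R1", "R3")))
  expect_equal(net$objective_rank, 0)
  aset <- enumerate_alternatives(prep$model, prep$task)
  expect_equal(aset$msize, 2)
  expect_equal(lapply(aset$networks, function(n) n$active_reactions),
               list(c("R1", "R2"), c("R1", "R3")))
  expect_identical(aset$hfrs, "R1")
  expect_equal(aset$hfr_fraction, 50)
})

test_that("a linear chain has a single alternative covering the chain", {
  chain <- make_parallel_gem(branches_per_stage = c(1L, 1L, 1L, 1L, 1L),
                             branch_length = 1L, seed = 2)
  prep <- prepare_task(split_reversible(chain$model), chain$task)
  aset <- enumerate_alternatives(prep$model, prep$task)
  expect_length(aset$networks, 1)
  expect_equal(aset$msize, 6)   # source + 5 stage reactions
  expect_identical(aset$hfrs, aset$networks[[1]]$active_reactions)
  expect_equal(aset$hfr_fraction, 100)
})

test_that("flux witnesses satisfy mass balance, the yield floor and support", {
  for (seed in 1:3) {
    fx <- make_parallel_gem(c(2L, 2L), branch_length = 2L, n_decoys = 2L,
                            cofactor_stages = 1L, seed = seed)
    prep <- prepare_task(split_reversible(fx$model), fx$task)
    aset <- enumerate_alternatives(prep$model, prep$task)
    S <- as.matrix(prep$model$stoich)
    floor_v <- prep$task$c * prep$task$v_mt_max
    for (net in aset$networks) {
      w <- net$flux_witness
      expect_lt(max(abs(S %*% w[colnames(S)])), 1e-6)
      expect_gte(w[[prep$task$demand_id]], floor_v - 1e-6)
      carrying <- setdiff(unique(prep$model$reactions$parent_id[
        match(names(w)[abs(w) > 1e-6], prep$model$reactions$id)]),
        prep$task$demand_id)
      expect_setequal(carrying, net$active_reactions)
      expect_equal(net$size, length(net$active_reactions))
    }
  }
})

test_that("rank-0 networks are subset-minimal: no single reaction is removable", {
  fx <- make_parallel_gem(c(3L), branch_length = 2L, n_decoys = 2L, seed = 5)
  prep <- prepare_task(split_reversible(fx$model), fx$task)
  aset <- enumerate_alternatives(prep$model, prep$task)
  floor_v <- prep$task$c * prep$task$v_mt_max
  rid <- prep$model$reactions$id
  parent <- prep$model$reactions$parent_id
  for (net in aset$networks) {
    for (drop in net$active_reactions) {
      keep <- setdiff(net$active_reactions, drop)
      off <- rid[!(parent %in% c(keep, prep$task$demand_id))]
      res <- fba_max(prep$model, prep$task$demand_id, zero_out = off)
      expect_lt(res$value, floor_v - 1e-6)
    }
  }
})

test_that("both directions of a split pair are never simultaneously active", {
  m <- toy_chain_model(rev_mid = TRUE)
  prep <- prepare_task(split_reversible(m), minea_task("C_SYN", "C"))
  aset <- enumerate_alternatives(prep$model, prep$task)
  for (net in aset$networks) {
    w <- net$flux_witness
    expect_false(w[["R2_fwd"]] > 1e-6 && w[["R2_rev"]] > 1e-6)
  }
  # parent-level reporting collapses the pair
  expect_true("R2" %in% aset$networks[[1]]$active_reactions)
})

test_that("enumeration is deterministic across repeated runs", {
  fx <- make_parallel_gem(c(2L, 3L), n_decoys = 2L, seed = 11)
  prep <- prepare_task(split_reversible(fx$model), fx$task)
  a1 <- enumerate_alternatives(prep$model, prep$task)
  a2 <- enumerate_alternatives(prep$model, prep$task)
  expect_identical(lapply(a1$networks, function(n) n$active_reactions),
                   lapply(a2$networks, function(n) n$active_reactions))
  expect_identical(a1$hfrs, a2$hfrs)
})

test_that("max_rank extends enumeration to near-minimal networks", {
  # two branches of length 1 plus one branch of length 2 between the same
  # metabolites: msize uses a short branch; msize+1 networks use the long one
  mets <- data.frame(id = c("A", "B"), compartment = "c")
  rxn <- data.frame(id = c("SRC", "P1", "P2", "L1", "L2"), lb = 0, ub = 1000)
  mets <- rbind(mets, data.frame(id = "I", compartment = "c"))
  stoich <- data.frame(
    metabolite = c("A", "A", "B", "A", "B", "A", "I", "I", "B"),
    reaction = c("SRC", "P1", "P1", "P2", "P2", "L1", "L1", "L2", "L2"),
    coefficient = c(1, -1, 1, -1, 1, -1, 1, -1, 1))
  m <- minea_model("ranked", mets, rxn, stoich)
  prep <- prepare_task(split_reversible(m), minea_task("B_SYN", "B"))
  strict <- enumerate_alternatives(prep$model, prep$task, max_rank = 0L)
  expect_equal(strict$msize, 2)
  expect_length(strict$networks, 2)
  wider <- enumerate_alternatives(prep$model, prep$task, max_rank = 1L)
  expect_length(wider$networks, 3)
  ranks <- vapply(wider$networks, function(n) n$objective_rank, numeric(1))
  expect_setequal(ranks, c(0, 0, 1))
  long <- wider$networks[[which(ranks == 1)[1]]]
  expect_setequal(long$active_reactions, c("SRC", "L1", "L2"))
})

test_that("the enumeration cap truncates with a warning", {
  fx <- make_parallel_gem(c(3L, 3L), seed = 8)
  prep <- prepare_task(split_reversible(fx$model), fx$task)
  expect_warning(aset <- enumerate_alternatives(prep$model, prep$task,
                                                cap = 4L),
                 "cap")
  expect_true(aset$truncated)
  expect_length(aset$networks, 4)
  expect_warning(phenotypic_hfrs(list(aset)), "approximate")
})

test_that("phenotypic HFRs are the intersection across tasks of a phenotype", {
  fx <- make_parallel_gem(c(2L, 1L), branch_length = 1L, seed = 9)
  prep <- prepare_task(split_reversible(fx$model), fx$task)
  aset <- enumerate_alternatives(prep$model, prep$task)
  # single task: equals that task's HFRs
  expect_identical(phenotypic_hfrs(list(aset)), aset$hfrs)
  # second task on the same model sharing the backbone up to M1
  task2 <- minea_task("MID", "M1", phenotype = "synthetic")
  prep2 <- prepare_task(prep$model, task2)
  aset2 <- enumerate_alternatives(prep2$model, prep2$task)
  shared <- phenotypic_hfrs(list(aset, aset2))
  expect_identical(shared, intersect(aset$hfrs, aset2$hfrs))
  expect_true("SRC" %in% shared)
  expect_error(phenotypic_hfrs(list()), "empty")
})

test_that("subsystem summaries count active members per annotation", {
  m <- load_model(extdata_path("toy_model.json"))
  prep <- prepare_task(split_reversible(m), minea_task("D_SYN", "D_c"))
  net <- solve_min_network(prep$model, prep$task)
  tab <- subsystem_summary(net, prep$model)
  expect_equal(tab$active[tab$subsystem == "lower pathway"], 2)
  expect_equal(tab$total[tab$subsystem == "lower pathway"], 2)
  expect_equal(tab$active[tab$subsystem == "upper pathway"], 1)
  expect_equal(tab$total[tab$subsystem == "upper pathway"], 2)
  # empty set: all active counts zero
  empty <- subsystem_summary(character(0), prep$model)
  expect_true(all(empty$active == 0))
})

test_that("infeasible tasks are reported as such", {
  m <- toy_chain_model()
  blocked <- m
  blocked$reactions$ub[blocked$reactions$id == "R1"] <- 0
  prep <- prepare_task(split_reversible(blocked), minea_task("C_SYN", "C"))
  expect_equal(prep$task$v_mt_max, 0)
  expect_error(solve_min_network(prep$model, prep$task), "infeasible")
})
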