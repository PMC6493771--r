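test_that("configuration validation names each problem", {
  cfg <- minea_config(model = extdata_path("toy_model.json"),
                      tasks = extdata_path("toy_tasks.tsv"))
  expect_length(validate_config(cfg), 0)
  bad <- cfg
  bad$c <- 0
  expect_match(validate_config(bad), "c must be in \\(0,1\\]", all = FALSE)
  bad <- cfg
  bad$alpha_rxn <- 1.5
  expect_match(validate_config(bad), "alpha_rxn", all = FALSE)
  bad <- cfg
  bad$deg <- c(x = "/nonexistent/deg.tsv")
  expect_match(validate_config(bad), "DEG table not found", all = FALSE)
  expect_match(validate_config(minea_config()), "model is required",
               all = FALSE)
  # defaults preserved when unset
  expect_equal(cfg$alpha_rxn, 0.005)
  expect_equal(cfg$alpha_gene, 0.05)
  expect_equal(cfg$c, 0.8)
  expect_error(run_enumerate(minea_config()), "invalid configuration")
})

test_that("TOML configuration files map onto the run configuration", {
  path <- tempfile(fileext = ".toml")
  writeLines(c(
    sprintf('model = "%s"', extdata_path("toy_model.json")),
    sprintf('tasks = "%s"', extdata_path("toy_tasks.tsv")),
    'c = 0.9', 'max_rank = 1',
    '[deg]',
    sprintf('demo_vs_ctrl = "%s"', extdata_path("toy_deg.tsv"))), path)
  cfg <- read_config(path)
  expect_equal(cfg$c, 0.9)
  expect_equal(cfg$max_rank, 1)
  expect_named(cfg$deg, "demo_vs_ctrl")
  expect_length(validate_config(cfg), 0)
})

test_that("the full pipeline writes all artifacts and is byte-reproducible", {
  out1 <- tempfile(); out2 <- tempfile()
  cfg <- minea_config(model = extdata_path("toy_model.json"),
                      tasks = extdata_path("toy_tasks.tsv"),
                      deg = c(demo_vs_ctrl = extdata_path("toy_deg.tsv")),
                      directionality = extdata_path("toy_directionality.tsv"),
                      out_dir = out1)
  res <- run_minea(cfg)
  for (f in c("minea_summary.tsv", "minea_networks.tsv", "minea_aminf.tsv",
              "minea_hfr_regulation.tsv", "run_manifest.json",
              "alternatives_D_SYN.json", "alternatives_B_SYN.json")) {
    expect_true(file.exists(file.path(out1, f)), info = f)
  }
  expect_equal(res$summary$msize[res$summary$task == "D_SYN"], 4)
  expect_equal(res$summary$n_alternatives[res$summary$task == "D_SYN"], 2)
  cfg2 <- cfg; cfg2$out_dir <- out2
  run_minea(cfg2)
  for (f in c("minea_summary.tsv", "minea_networks.tsv", "minea_aminf.tsv",
              "minea_hfr_regulation.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("saved enumerations reload and re-score identically", {
  out <- tempfile()
  cfg <- minea_config(model = extdata_path("toy_model.json"),
                      tasks = extdata_path("toy_tasks.tsv"),
                      deg = c(demo_vs_ctrl = extdata_path("toy_deg.tsv")),
                      out_dir = out)
  enum <- run_enumerate(cfg)
  reloaded <- load_alternatives(list.files(out, "^alternatives_.*json$",
                                           full.names = TRUE))
  expect_setequal(names(reloaded), c("D_SYN", "B_SYN"))
  expect_equal(reloaded$D_SYN$msize, enum$alt_sets$D_SYN$msize)
  expect_identical(
    lapply(reloaded$D_SYN$networks, function(n) n$active_reactions),
    lapply(enum$alt_sets$D_SYN$networks, function(n) n$active_reactions))
  rep1 <- run_enrich(cfg, enum$model, enum$alt_sets)
  rep2 <- run_enrich(cfg, enum$model, reloaded)
  expect_equal(rep1$aminf$aminf, rep2$aminf$aminf)
})

test_that("a missing DEG file fails cleanly, naming the path", {
  cfg <- minea_config(model = extdata_path("toy_model.json"),
                      tasks = extdata_path("toy_tasks.tsv"),
                      deg = c(x = "/no/such/deg.tsv"),
                      out_dir = tempfile())
  expect_error(run_minea(cfg), "/no/such/deg.tsv")
})

test_that("planted-fixture pipeline recovers the ground truth end to end", {
  fx <- make_parallel_gem(c(3L), branch_length = 4L, n_decoys = 11L,
                          seed = 31)
  dir <- tempfile(); dir.create(dir)
  model_path <- file.path(dir, "model.json")
  write_model_json(fx$model, model_path)
  tasks_path <- file.path(dir, "tasks.tsv")
  writeLines(c("task_name\tmetabolite_id\tcompartment\tphenotype",
               sprintf("TARGET\t%s\tc\tsynthetic", fx$task$metabolite)),
             tasks_path)
  branch <- grep("^S1B2", fx$model$reactions$id, value = TRUE)
  calls <- plant_regulation(fx$model, branch, "up", background_rate = 0,
                            seed = 1)
  deg_path <- file.path(dir, "deg.tsv")
  writeLines(c("gene_id\tdirection",
               paste(names(calls), calls, sep = "\t")), deg_path)
  cfg <- minea_config(model = model_path, tasks = tasks_path,
                      deg = c(planted = deg_path),
                      out_dir = file.path(dir, "out"))
  res <- run_minea(cfg)
  expect_equal(res$summary$n_alternatives, fx$truth$n_alternatives)
  expect_equal(res$summary$msize, fx$truth$msize)
  nets <- res$report$networks
  planted_net <- vapply(res$alt_sets$TARGET$networks,
                        function(n) all(branch %in% n$active_reactions),
                        logical(1))
  expect_equal(nets$p_up < 0.005, planted_net)
  aminf_up <- res$report$aminf$aminf[res$report$aminf$mode == "up"]
  expect_equal(aminf_up, 1 / 3)
})

test_that("the command-line wrapper drives the pipeline from a shell", {
  cli <- system.file("cli", "minea.R", package = "minea")
  if (!nzchar(cli)) cli <- "../../inst/cli/minea.R"
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- tempfile(); dir.create(dir)
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- system2(rscript, c(cli, "synth", "--branches", "2", "--decoys", "1",
                            "--plant-branch", "S1B1", "--seed", "4",
                            "--out", dir),
                 env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "model.json")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  out2 <- system2(rscript, c(cli, "run", "--model",
                             file.path(dir, "model.json"),
                             "--tasks", file.path(dir, "tasks.tsv"),
                             "--deg", paste0("planted=",
                                             file.path(dir, "deg.tsv")),
                             "--out", file.path(dir, "out")),
                  env = env, stdout = TRUE, stderr = TRUE)
  status2 <- attr(out2, "status")
  expect_true(is.null(status2) || status2 == 0)
  expect_true(file.exists(file.path(dir, "out", "minea_summary.tsv")))
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  summary <- read.delim(file.path(dir, "out", "minea_summary.tsv"))
  expect_equal(summary$n_alternatives, truth$n_alternatives)
  expect_equal(summary$msize, truth$msize)
})
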