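test_that("experiment config validates its inputs", {
  expect_error(experiment_config(networks = "no-such-net.txt", n_mutants = 5,
                                 out_dir = tempdir()),
               "no-such-net.txt")
  expect_error(experiment_config(networks = list(n = 2), n_mutants = 5,
                                 out_dir = tempdir()),
               "file paths or list")
  expect_error(experiment_config(networks = list(n = 2, N = 5, K = 2),
                                 n_mutants = 0, out_dir = tempdir()),
               "n_mutants")
})

test_that("run_experiment writes a complete, reproducible artifact set", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  mk_cfg <- function(out) experiment_config(
    networks = list(n = 2, N = 6, K = 2), n_mutants = 6,
    perturbation = perturbation_config(T = 10, s = 16),
    out_dir = out, seed = 17, train = FALSE)
  man1 <- run_experiment(mk_cfg(out1), quiet = TRUE)
  expect_true(all(c("labels.tsv", "features.tsv") %in% man1$file))
  expect_true(any(grepl("^curves/", man1$file)))
  expect_true(any(grepl("^networks/", man1$file)))
  expect_true(file.exists(file.path(out1, "manifest.tsv")))
  labels <- read.delim(file.path(out1, "labels.tsv"))
  expect_equal(nrow(labels), 12L)
  feats <- read.delim(file.path(out1, "features.tsv"))
  expect_equal(nrow(feats), 12L)
  expect_equal(ncol(feats), 4L + 30L)
  # byte-identical rerun under the same seed
  man2 <- run_experiment(mk_cfg(out2), quiet = TRUE)
  expect_identical(man1$md5, man2$md5)
  expect_identical(unname(tools::md5sum(file.path(out1, "labels.tsv"))),
                   unname(tools::md5sum(file.path(out2, "labels.tsv"))))
})

test_that("summarize_experiment reports conservation and association", {
  out <- withr::local_tempdir()
  cfg <- experiment_config(networks = list(n = 2, N = 6, K = 2),
                           n_mutants = 8,
                           perturbation = perturbation_config(T = 10, s = 16),
                           out_dir = out, seed = 23, train = FALSE)
  run_experiment(cfg, quiet = TRUE)
  s <- summarize_experiment(out)
  expect_equal(sum(s$contingency), 16)         # networks x mutants
  expect_equal(unname(rowSums(s$class_distribution)), c(100, 100))
  expect_error(summarize_experiment(withr::local_tempdir()),
               "missing experiment artifacts")
})

test_that("the CLI drives generate, step, attractors, mutate and assoc", {
  dir <- withr::local_tempdir()
  netf <- file.path(dir, "net.txt")
  expect_output(bn_cli(c("generate", "--n", "5", "--k", "2", "--seed", "3",
                         "--out", netf)), "wrote")
  net <- read_network(netf)
  expect_equal(net$N, 5L)
  expect_output(bn_cli(c("step", "--net", netf, "--state", "10101",
                         "--steps", "2")), "t=2")
  repf <- file.path(dir, "attr.json")
  expect_output(bn_cli(c("attractors", "--net", netf, "--out", repf)))
  rep <- jsonlite::read_json(repf, simplifyVector = TRUE)
  expect_equal(rep$N, 5L)
  expect_equal(sum(rep$attractors$basin_size), 32L)
  mdir <- file.path(dir, "mutants")
  expect_output(bn_cli(c("mutate", "--net", netf, "--n", "8", "--seed", "2",
                         "--out-dir", mdir)), "8 mutants")
  labf <- file.path(dir, "labels.tsv")
  expect_output(bn_cli(c("classify", "--net", netf, "--mutants-dir", mdir,
                         "--out", labf)), "wrote")
  lab <- read.delim(labf)
  expect_equal(nrow(lab), 8L)
  expect_output(bn_cli(c("assoc", "--labels", labf)), "Cramer's V")
  # fragility + diffcurve round trip
  cf <- file.path(dir, "curve.tsv")
  expect_output(bn_cli(c("fragility", "--net", netf, "--T", "10", "--s", "16",
                         "--seed", "1", "--out", cf)), "wrote")
  df <- file.path(dir, "diff.tsv")
  expect_output(bn_cli(c("diffcurve", "--orig", cf, "--mut", cf,
                         "--out", df)), "wrote")
  dtab <- read.delim(df)
  expect_equal(nrow(dtab), 30L)
  expect_equal(dtab$value, rep(0, 30))
  expect_error(bn_cli(c("frobnicate")), "unknown command")
})
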