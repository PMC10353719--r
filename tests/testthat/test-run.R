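test_that("a perfect linear pair yields exactly one edge with signed dcor 1", {
  rt <- simulate_scenario("linear", 20, 2, noise_sd = 0, seed = 31)
  edges <- sidcor_run(rt, mode = "one_to_one", quiet = TRUE)
  expect_identical(nrow(edges), 1L)
  expect_equal(edges$signed_dcor, 1, tolerance = 1e-12)
  expect_equal(edges$p_dcor, 0)
  expect_identical(edges$mode, "one_to_one")
})

test_that("threshold validation rejects out-of-range config", {
  rt <- simulate_scenario("linear", 20, 2, seed = 31)
  expect_error(sidcor_run(rt, mode = "one_to_one", dcor_threshold = 1.01,
                          quiet = TRUE), "\\[0, 1\\]")
  expect_error(sidcor_run(rt, mode = "one_to_one", p_threshold = -0.1,
                          quiet = TRUE), "\\[0, 1\\]")
})

test_that("edge filtering reproduces hand-selected sets and fixed ordering", {
  edges <- tibble::tibble(
    feature_a = c("A", "A", "B", "B", "C", "A"),
    feature_b = c("B", "C", "C", "D", "D", "D"),
    dcor = c(0.9, 0.9, 0.5, 0.45, 0.2, 0.05),
    sign = c(1, -1, 1, 1, -1, 1),
    signed_dcor = c(0.9, -0.9, 0.5, 0.45, -0.2, 0.05),
    p_dcor = c(0.001, 0.002, 0.03, 0.06, 0.4, 0.9))
  out <- filter_edges(edges, dcor_threshold = 0.4, p_threshold = 0.05)
  expect_identical(out$feature_a, c("A", "A", "B"))
  expect_identical(out$feature_b, c("B", "C", "C"))  # ties broken lexically
  expect_identical(filter_edges(edges, 0, 1), edges[order(-edges$dcor,
    edges$feature_a, edges$feature_b), ])
  expect_identical(nrow(filter_edges(edges, 0, 0)), 0L)

  # BH adjustment shrinks the retained set monotonically
  raw <- filter_edges(edges, 0, 0.05)
  adj <- filter_edges(edges, 0, 0.05, adjust = "bh")
  expect_true(all(paste(adj$feature_a, adj$feature_b) %in%
                  paste(raw$feature_a, raw$feature_b)))
})

test_that("filtering is monotone in both thresholds", {
  edges <- sidcor_run(simulate_scenario("gaussian_chain", 40, 5, seed = 32),
                      mode = "one_to_one", quiet = TRUE)
  prev <- nrow(edges)
  for (thr in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    cur <- nrow(filter_edges(edges, dcor_threshold = thr))
    expect_lte(cur, prev)
    prev <- cur
  }
  prev <- nrow(edges)
  for (p in c(0.5, 0.1, 0.01, 0.001)) {
    cur <- nrow(filter_edges(edges, p_threshold = p))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("identical input and config give byte-identical CSV output", {
  rt <- simulate_scenario("gaussian_chain", 30, 4, seed = 33)
  path <- write_raw_csv(rt)
  out1 <- tempfile(fileext = ".csv")
  out2 <- tempfile(fileext = ".csv")
  sidcor_run(path, mode = "one_to_one", output = out1, quiet = TRUE)
  sidcor_run(path, mode = "one_to_one", output = out2, quiet = TRUE)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
})

test_that("the one-to-one matrix rebuilt from the edge table is symmetric", {
  fm <- random_fm(25, 5, seed = 34)
  edges <- sidcor_run(simulate_scenario("independent", 25, 5, seed = 34),
                      mode = "one_to_one", quiet = TRUE)
  m <- diag(1, 5)
  dimnames(m) <- list(paste0("F", 1:5), paste0("F", 1:5))
  for (k in seq_len(nrow(edges))) {
    m[edges$feature_a[k], edges$feature_b[k]] <- edges$dcor[k]
    m[edges$feature_b[k], edges$feature_a[k]] <- edges$dcor[k]
  }
  expect_identical(m, t(m))
  expect_equal(m, dcor_matrix(fm))
})

test_that("one-to-all and partial modes run end to end with their columns", {
  rt <- simulate_scenario("hub", 50, 4, seed = 35)
  oa <- sidcor_run(rt, mode = "one_to_all", quiet = TRUE)
  expect_identical(nrow(oa), 4L)
  expect_true(all(oa$feature_b == "ALL_OTHERS"))
  expect_true(all(oa$n_covariates == 3L))

  pa <- sidcor_run(rt, mode = "partial", quiet = TRUE)
  expect_identical(names(pa),
                   c("feature_a", "feature_b", "partial_rho", "z",
                     "p_partial", "mode"))
  expect_identical(nrow(pa), 6L)
})

test_that("constant features are excluded with a warning, not an error", {
  rt <- simulate_scenario("linear", 20, 4, seed = 36, constant_features = 1)
  expect_warning(edges <- sidcor_run(rt, mode = "one_to_one", quiet = TRUE),
                 "constant feature")
  expect_false("F4" %in% c(edges$feature_a, edges$feature_b))
  expect_identical(nrow(edges), 3L)
})

test_that("the command-line wrapper simulates and analyses a fixture", {
  exe <- system.file("exec", "sidcor", package = "sidcor")
  if (exe == "") exe <- file.path(find.package("sidcor"), "exec", "sidcor")
  expect_true(file.exists(exe))
  fixture <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  s1 <- system2("Rscript", c(exe, "simulate", "--scenario", "linear",
                             "--n", "20", "--m", "3", "--seed", "5",
                             "--output", fixture),
                env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(fixture))
  s2 <- system2("Rscript", c(exe, "run", "--mode", "one-to-one",
                             "--input", fixture, "--output", out,
                             "--dcor-threshold", "0", "--p-threshold", "1"),
                env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  got <- readr::read_csv(out, show_col_types = FALSE, progress = FALSE)
  want <- sidcor_run(simulate_scenario("linear", 20, 3, seed = 5),
                     mode = "one_to_one", quiet = TRUE)
  expect_equal(got$dcor, want$dcor, tolerance = 1e-12)

  bad <- suppressWarnings(
    system2("Rscript", c(exe, "run", "--mode", "one-to-one",
                            "--input", "/nonexistent.csv",
                            "--output", out),
            env = env, stdout = TRUE, stderr = TRUE))
  expect_identical(attr(bad, "status"), 1L)
})
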