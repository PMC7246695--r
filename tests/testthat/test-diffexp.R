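make_norm <- function(values, samples) {
  matrix(values, nrow = length(values) / length(samples),
         ncol = length(samples), byrow = TRUE,
         dimnames = list(paste0("g", seq_len(length(values) / length(samples))),
                         samples))
}

test_that("identical groups give the null result and all-zero genes degenerate", {
  n <- rbind(g1 = c(10, 12, 10, 12), g2 = c(0, 0, 0, 0))
  colnames(n) <- c("a1", "a2", "b1", "b2")
  res <- nb_wald_test(n, c("a1", "a2"), c("b1", "b2"))
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("Wald statistics match the formula oracle at fixed dispersion", {
  n <- rbind(g1 = c(95, 105, 790, 810),
             g2 = c(40, 60, 45, 55))
  colnames(n) <- c("a1", "a2", "b1", "b2")
  res <- nb_wald_test(n, c("a1", "a2"), c("b1", "b2"),
                      pseudocount = 0.5, dispersion = c(0.05, 0.05))
  o1 <- wald_oracle(100, 800, 2, 2, 0.05, 0.5)
  o2 <- wald_oracle(50, 50, 2, 2, 0.05, 0.5)
  expect_equal(res$log2fc, c(o1$log2fc, o2$log2fc), tolerance = 1e-10)
  expect_equal(res$p, c(o1$p, o2$p), tolerance = 1e-10)
  # approximately 3 log2 units, shrunk slightly by the pseudocount
  expect_equal(res$log2fc[1], 3, tolerance = 0.01)
})

test_that("BH adjustment equals the step-up oracle on all permutations of 6", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  base <- c(0.001, 0.02, 0.02, 0.3, 0.6, 1)
  perms <- NULL
  for (a in 1:6) for (b in setdiff(1:6, a)) for (cc in setdiff(1:6, c(a, b)))
    for (d in setdiff(1:6, c(a, b, cc)))
      for (e in setdiff(1:6, c(a, b, cc, d))) {
        perms <- rbind(perms, c(a, b, cc, d, e, setdiff(1:6, c(a, b, cc, d, e))))
      }
  for (i in seq_len(nrow(perms))) {
    p <- base[perms[i, ]]
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # monotone when sorted by p
  set.seed(5)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p))
})

test_that("run_contrasts produces the five labeled contrasts with q >= p", {
  cfg <- sim_config(n_genes = 300, seed = 3,
                    planted = c(PROPER_UP = 15L, PROPER_DOWN = 15L,
                                REFRACTORY_UP = 10L, WRONG_UP = 10L))
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth, cfg)
  n <- normalize_counts(sim$counts, size_factors(sim$counts))
  ctr <- run_contrasts(n, sim$samples)
  expect_named(ctr, c("E_vs_F", "R48_vs_F", "R72_vs_F",
                      "R48_vs_G48", "R72_vs_G72"))
  for (cr in ctr) {
    expect_true(all(cr$q >= cr$p - 1e-12))
    expect_true(all(cr$q >= 0 & cr$q <= 1))
    expect_true(all(is.finite(cr$log2fc)))
  }
})

test_that("null p-values are near-uniform and a planted 8-fold gene is called", {
  # all-states-equal null across the full design
  cfg <- sim_config(n_genes = 2000, planted = c(PROPER_UP = 0L), seed = 17)
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth, cfg)
  n <- normalize_counts(sim$counts, size_factors(sim$counts))
  ctr <- run_contrasts(n, sim$samples)
  p <- ctr$R48_vs_F$p
  ks <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks, 0.05)
  expect_lt(mean(ctr$E_vs_F$q < 0.01), 0.01)

  # plant one strong ESC-enriched gene among nulls
  set.seed(23)
  sheet <- study_sheet()
  mu <- matrix(400, 500, nrow(sheet),
               dimnames = list(sprintf("g%03d", 1:500), sheet$sample_id))
  mu[1, sheet$sample_id[sheet$state == "ESC"]] <- 3200
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  ctr <- run_contrasts(counts, sheet)   # factors ~1, use counts directly
  expect_lt(ctr$E_vs_F$q[1], 0.01)
  expect_gt(ctr$E_vs_F$log2fc[1], log2(2))
})

test_that("consistent response requires all four contrasts and both baselines", {
  sheet <- study_sheet()
  summ <- data.frame(gene_id = c("g1", "g2", "g3"),
                     F_mean = c(100, 100, 10), E_mean = c(800, 800, 200),
                     R48_mean = c(700, 700, 35), R72_mean = c(650, 650, 30),
                     G48_mean = c(100, 100, 11), G72_mean = c(100, 100, 9),
                     expressed_FIB = TRUE, expressed_ESC = TRUE)
  mk <- function(lfc, q) data.frame(gene_id = summ$gene_id, log2fc = lfc,
                                    p = q, q = q)
  ctr <- list(R48_vs_F = mk(c(2.5, 2.5, 1.8), c(1e-6, 1e-6, 1e-6)),
              R72_vs_F = mk(c(2.5, 2.5, 1.6), c(1e-6, 1e-6, 1e-6)),
              R48_vs_G48 = mk(c(2.5, 2.5, 1.7), c(1e-6, 0.02, 1e-6)),
              R72_vs_G72 = mk(c(2.5, 2.5, 1.6), c(1e-6, 1e-6, 1e-6)))
  resp <- consistent_response(ctr, summ)
  expect_equal(resp$response, c("UP", "NONE", "NONE"))
  # g2 fails only on one GFP-baseline q; g3 is a >2-fold change whose
  # expression stays below 50 with and without OSKM, forced to NONE
  expect_true(resp$sub_threshold[3])
  expect_false(resp$sub_threshold[1])
})

test_that("weakening any single contrast never creates a response", {
  set.seed(42)
  sheet <- study_sheet()
  for (i in 1:40) {
    lfc <- runif(4, -3, 3)
    q <- runif(4, 0, 0.05)
    summ <- data.frame(gene_id = "g", F_mean = 100, E_mean = 100,
                       R48_mean = 400, R72_mean = 400, G48_mean = 100,
                       G72_mean = 100, expressed_FIB = TRUE,
                       expressed_ESC = TRUE)
    mk <- function(j) data.frame(gene_id = "g", log2fc = lfc[j], p = q[j],
                                 q = q[j])
    ctr <- list(R48_vs_F = mk(1), R72_vs_F = mk(2),
                R48_vs_G48 = mk(3), R72_vs_G72 = mk(4))
    before <- consistent_response(ctr, summ)$response
    j <- sample(4, 1)
    weakened <- ctr
    weakened[[j]]$q <- 0.5
    weakened[[j]]$log2fc <- weakened[[j]]$log2fc / 10
    after <- consistent_response(weakened, summ)$response
    if (before == "NONE") expect_equal(after, "NONE")
  }
})

test_that("imported contrasts reproduce the internal downstream result", {
  cfg <- sim_config(n_genes = 400, seed = 9,
                    planted = c(PROPER_UP = 25L, PROPER_DOWN = 25L,
                                REFRACTORY_UP = 15L, UNWANTED_UP = 15L,
                                WRONG_DOWN = 10L))
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth, cfg)
  res <- piano_run(sim$counts, sim$samples)
  d <- withr::local_tempdir()
  paths <- vapply(names(res$contrasts), function(nm) {
    p <- file.path(d, paste0(nm, ".tsv"))
    write.table(res$contrasts[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }, character(1))
  imported <- import_contrasts(paths, gene_ids = rownames(sim$counts))
  res2 <- piano_run(sim$counts, sim$samples, contrasts = imported)
  expect_equal(as.character(res2$piano_table$category),
               as.character(res$piano_table$category))

  # missing column is named
  broken <- res$contrasts$E_vs_F[, c("gene_id", "log2fc", "p")]
  write.table(broken, paths[["E_vs_F"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(import_contrasts(paths), "q")

  # absent genes become non-significant
  trimmed <- res$contrasts$E_vs_F[-1, ]
  write.table(trimmed, paths[["E_vs_F"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  imp <- import_contrasts(paths, gene_ids = rownames(sim$counts))
  miss <- setdiff(rownames(sim$counts), trimmed$gene_id)
  expect_equal(imp$E_vs_F$q[imp$E_vs_F$gene_id == miss], 1)
})
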