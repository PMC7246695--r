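test_that("the scalar classifier reproduces the 14-category hand fixture", {
  df <- hand_fixture()
  got <- vapply(seq_len(nrow(df)), function(i) {
    classify_gene(df$F_mean[i], df$E_mean[i], df$R48_mean[i], df$R72_mean[i],
                  df$response[i], df$in_up_set[i], df$in_down_set[i],
                  df$in_up_high[i], df$in_down_high[i])
  }, character(1))
  expect_equal(got, df$expected)
})

test_that("classify_all agrees with the fixture and is order-invariant", {
  df <- hand_fixture()
  parts <- fixture_parts(df)
  tab <- classify_all(parts$summ, parts$response, parts$reprog)
  expect_equal(as.character(tab$category), df$expected)
  expect_s3_class(tab$category, "factor")
  expect_identical(levels(tab$category), PIANO_CATEGORIES)

  set.seed(31)
  ord <- sample(nrow(df))
  parts2 <- fixture_parts(df[ord, ])
  tab2 <- classify_all(parts2$summ, parts2$response, parts2$reprog)
  expect_equal(as.character(tab2$category)[order(ord)],
               as.character(tab$category))
})

test_that("membership in both sub-reprogramomes is an upstream error", {
  expect_error(classify_gene(10, 100, 50, 50, "UP", TRUE, TRUE),
               "both sub-reprogramomes")
  df <- hand_fixture()
  df$in_down_set[1] <- TRUE
  parts <- fixture_parts(df)
  expect_error(classify_all(parts$summ, parts$response, parts$reprog),
               "both sub-reprogramomes")
})

test_that("classify_all equals the scalar classifier on random genes", {
  set.seed(77)
  n <- 1000
  lu <- function(a, b) exp(runif(n, log(a), log(b)))
  df <- data.frame(gene_id = sprintf("r%04d", 1:n),
                   F_mean = lu(1, 5000), E_mean = lu(1, 5000),
                   R48_mean = lu(1, 5000), R72_mean = lu(1, 5000),
                   response = sample(c("UP", "DOWN", "NONE"), n, TRUE),
                   stringsAsFactors = FALSE)
  memb <- sample(c("up", "down", "none"), n, TRUE)
  df$in_up_set <- memb == "up"
  df$in_down_set <- memb == "down"
  df$in_up_high <- runif(n) < 0.2
  df$in_down_high <- !df$in_up_high & runif(n) < 0.2
  df$expected <- NA_character_
  parts <- fixture_parts(df)
  tab <- classify_all(parts$summ, parts$response, parts$reprog)
  scalar <- vapply(seq_len(n), function(i) {
    classify_gene(df$F_mean[i], df$E_mean[i], df$R48_mean[i], df$R72_mean[i],
                  df$response[i], df$in_up_set[i], df$in_down_set[i],
                  df$in_up_high[i], df$in_down_high[i])
  }, character(1))
  expect_equal(as.character(tab$category), scalar)
  # structural invariants of the partition
  cc <- as.character(tab$category)
  expect_true(all(cc[df$response == "NONE"] %in%
                    c("REFRACTORY_UP", "REFRACTORY_DOWN", "OUT_OF_SCOPE")))
  expect_true(all(df$in_down_set[cc == "WRONG_UP"]))
  expect_true(all(df$in_up_set[cc == "WRONG_DOWN"]))
  expect_true(all(!df$in_up_set[cc == "UNWANTED_UP"] &
                    !df$in_down_set[cc == "UNWANTED_UP"]))
  expect_true(all(df$in_up_high[cc == "REFRACTORY_UP"]))
})

test_that("timepoint disagreement inside the upreprogramome is TRANSITIONAL", {
  # 48 h inside the ESC band, 72 h collapsed below it
  expect_equal(classify_gene(50, 400, 500, 100, "UP", TRUE, FALSE),
               "TRANSITIONAL")
  # responsive but outside both sets with a real E/F difference
  expect_equal(classify_gene(50, 400, 500, 450, "UP", FALSE, FALSE),
               "TRANSITIONAL")
})

test_that("summary arithmetic: counts, totals, percentages, zero denominators", {
  planted <- c(PROPER_UP = 366L, PROPER_DOWN = 213L,
               INSUFFICIENT_UP = 152L, INSUFFICIENT_DOWN = 286L,
               REFRACTORY_UP = 504L, REFRACTORY_DOWN = 449L,
               WRONG_UP = 22L, WRONG_DOWN = 26L,
               UNWANTED_UP = 134L, UNWANTED_DOWN = 99L,
               OVER_UP = 18L, OVER_DOWN = 6L, OUT_OF_SCOPE = 100L)
  tab <- data.frame(
    gene_id = sprintf("g%04d", seq_len(sum(planted))),
    category = factor(rep(names(planted), planted),
                      levels = PIANO_CATEGORIES))
  response <- data.frame(
    gene_id = tab$gene_id,
    response = c(rep("UP", 946), rep("DOWN", 800),
                 rep("NONE", nrow(tab) - 1746)))
  reprog <- list(up_high = sprintf("u%04d", 1:1033),
                 down_high = sprintf("d%04d", 1:1129))
  s <- piano_summarize(tab, response, reprog)
  expect_equal(unname(s$counts[names(planted)]), unname(planted))
  expect_equal(unname(s$totals["proper_total"]), 579)
  expect_equal(unname(s$totals["insufficient_total"]), 438)
  expect_equal(unname(s$totals["refractory_total"]), 953)
  expect_equal(unname(s$totals["aberrant_total"]), 305)
  p <- s$percentages
  expect_equal(p$value[p$quantity == "proper_up_of_upregulated"], 38.7)
  expect_equal(p$value[p$quantity == "refractory_up_of_up_high"], 48.8)
  expect_equal(p$value[p$quantity == "refractory_down_of_down_high"], 39.8)
  expect_equal(s$aux$n_up, 946)

  flat <- summary_table(s)
  expect_equal(flat$value[flat$quantity == "PROPER_UP"], 366)
  expect_equal(flat$value[flat$quantity == "aberrant_total"], 305)

  # empty high pools and no responders: NA, never divide by zero
  reprog0 <- list(up_high = character(0), down_high = character(0))
  response0 <- data.frame(gene_id = tab$gene_id, response = "NONE")
  s0 <- piano_summarize(tab, response0, reprog0)
  expect_true(all(is.na(s0$percentages$value)))
})

test_that("report_percentage rounds half-up to one decimal", {
  expect_equal(report_percentage(366, 946), 38.7)
  expect_equal(report_percentage(115, 238), 48.3)
  expect_equal(report_percentage(83, 115), 72.2)
  expect_equal(report_percentage(54, 83), 65.1)
  expect_equal(report_percentage(44, 54), 81.5)
  # .x5 cases go up, not to even
  expect_equal(report_percentage(1, 16), 6.3)
  expect_equal(report_percentage(5, 8), 62.5)
  expect_true(is.na(report_percentage(3, 0)))
})

test_that("union-style DE counts tally either-timepoint hits", {
  mk <- function(lfc, q) data.frame(gene_id = c("a", "b", "c"),
                                    log2fc = lfc, p = q, q = q)
  ctr <- list(
    R48_vs_F = mk(c(2, 0.5, -3), c(1e-5, 1e-5, 0.5)),
    R72_vs_F = mk(c(0.1, 0.2, -3), c(0.9, 0.9, 1e-5)),
    R48_vs_G48 = mk(c(0, 0, 0), c(1, 1, 1)),
    R72_vs_G72 = mk(c(0, 0, 0), c(1, 1, 1)))
  resp <- data.frame(gene_id = c("a", "b", "c"), response = "NONE")
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    category = factor("OUT_OF_SCOPE",
                                      levels = PIANO_CATEGORIES))
  s <- piano_summarize(tab, resp, list(up_high = character(0),
                                       down_high = character(0)),
                       contrasts = ctr)
  # a hits at 48 h only, b never (fold too small / q too large), c at 72 h
  expect_equal(s$aux$union_de_vs_F, 2)
  expect_equal(s$aux$union_de_vs_G, 0)
})
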