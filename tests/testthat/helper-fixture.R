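hand_fixture <- function() {
  # one row per category, each engineered to satisfy exactly one leaf of
  # the decision tree at default thresholds
  df <- data.frame(
    gene_id = paste0("hx", 1:14),
    expected = c("PROPER_UP", "PROPER_DOWN", "INSUFFICIENT_UP",
                 "INSUFFICIENT_DOWN", "REFRACTORY_UP", "REFRACTORY_DOWN",
                 "WRONG_UP", "WRONG_DOWN", "UNWANTED_UP", "UNWANTED_DOWN",
                 "OVER_UP", "OVER_DOWN", "TRANSITIONAL", "OUT_OF_SCOPE"),
    F_mean = c(50, 1000, 20, 5000, 100, 2000, 500, 60, 200, 400, 100, 800,
               50, 75),
    E_mean = c(800, 30, 2000, 60, 900, 80, 50, 700, 200, 400, 400, 100,
               400, 75),
    R48_mean = c(700, 40, 500, 300, 105, 1900, 2000, 60, 900, 50, 900, 40,
                 500, 70),
    R72_mean = c(650, 20, 400, 250, 95, 2100, 1800, 50, 850, 45, 850, 30,
                 100, 80),
    response = c("UP", "DOWN", "UP", "DOWN", "NONE", "NONE", "UP", "DOWN",
                 "UP", "DOWN", "UP", "DOWN", "UP", "NONE"),
    in_up_set = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                  FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    in_down_set = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                    FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    in_up_high = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    in_down_high = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  df
}

fixture_parts <- function(df) {
  list(
    summ = data.frame(gene_id = df$gene_id, F_mean = df$F_mean,
                      E_mean = df$E_mean, R48_mean = df$R48_mean,
                      R72_mean = df$R72_mean,
                      G48_mean = df$F_mean, G72_mean = df$F_mean,
                      expressed_FIB = df$F_mean > 50,
                      expressed_ESC = df$E_mean > 50),
    response = data.frame(gene_id = df$gene_id, response = df$response,
                          sub_threshold = FALSE),
    reprog = structure(list(
      up_set = df$gene_id[df$in_up_set],
      down_set = df$gene_id[df$in_down_set],
      up_high = df$gene_id[df$in_up_high],
      down_high = df$gene_id[df$in_down_high],
      evidence = data.frame(gene_id = df$gene_id,
                            in_up_set = df$in_up_set,
                            in_down_set = df$in_down_set,
                            in_up_high = df$in_up_high,
                            in_down_high = df$in_down_high)),
      class = "reprogramome"))
}
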