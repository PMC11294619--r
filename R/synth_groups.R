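#' Generate a two-group measurement table with a known true effect
#'
#' Draws two normal samples — a control group and a test group whose mean is
#' shifted by `effect` — in the long per-hemisphere table layout used
#' throughout the pipeline (columns: group, hemisphere, variable, value).
#' The true mean difference (test - control) is recorded as ground truth.
#'
#' @param n_control,n_test Group sizes (>= 2 each; a two-sample t-test is
#'   undefined below that).
#' @param control_mean Mean of the control group.
#' @param effect True mean difference added to the test group.
#' @param sd Common within-group SD (>= 0; 0 gives the degenerate
#'   noise-free limit).
#' @param seed Integer seed.
#' @param variable Variable name for the `variable` column.
#' @param labels Character pair: control and test group labels.
#' @return List with `table` (data.frame: group, hemisphere, variable,
#'   value) and `truth` (list with `true_mean_difference`).
#' @export
generate_group_table <- function(n_control, n_test, control_mean, effect, sd,
                                 seed, variable = "measure",
                                 labels = c("control", "test")) {
  n_control <- as.integer(n_control); n_test <- as.integer(n_test)
  if (n_control < 2L || n_test < 2L) {
    stop("each group needs n >= 2 (t-test undefined otherwise)")
  }
  if (sd < 0) stop("sd must be >= 0")
  set.seed(as.integer(seed))
  vc <- stats::rnorm(n_control, control_mean, sd)
  vt <- stats::rnorm(n_test, control_mean + effect, sd)
  tab <- data.frame(
    group = rep(labels, c(n_control, n_test)),
    hemisphere = c(sprintf("%s_h%02d", labels[1L], seq_len(n_control)),
                   sprintf("%s_h%02d", labels[2L], seq_len(n_test))),
    variable = variable,
    value = c(vc, vt),
    stringsAsFactors = FALSE)
  list(table = tab, truth = list(true_mean_difference = effect))
}
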