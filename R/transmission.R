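#' Homoeolog bias states
#' @export
bias_states <- c("A_gt_C", "A_eq_C", "A_lt_C")

#' The nine transmission patterns and their groups
#'
#' Fixed enumeration of the 3 x 3 parental-state by progeny-state grid.
#' Group A (patterns I-III) is parental legacy: the progeny inherits the
#' parental bias state. Group B (IV-V): a parental bias is lost (progeny
#' becomes balanced). Group C (VI-IX): the progeny shows a bias novel
#' relative to the parents (gained or reversed). Emitted in output headers
#' so results are self-describing.
#'
#' @export
transmission_patterns <- data.frame(
  pattern = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX"),
  parental = c("A_gt_C", "A_eq_C", "A_lt_C", "A_gt_C", "A_lt_C",
               "A_eq_C", "A_eq_C", "A_gt_C", "A_lt_C"),
  progeny = c("A_gt_C", "A_eq_C", "A_lt_C", "A_eq_C", "A_eq_C",
              "A_gt_C", "A_lt_C", "A_lt_C", "A_gt_C"),
  group = c("A", "A", "A", "B", "B", "C", "C", "C", "C"),
  stringsAsFactors = FALSE)

#' Derive a bias state from a divergence test
#'
#' A homoeolog pair is balanced (`A_eq_C`) when its A-vs-C divergence test
#' is non-significant (`q >= alpha`); otherwise the sign of the divergence
#' names the dominant homoeolog. A significant test with sign zero is
#' contradictory input and errors.
#'
#' @param q FDR-adjusted q-values in \[0, 1\].
#' @param sign Signed divergence (any signed value; only the sign is used).
#' @param alpha Significance threshold (default 0.05).
#' @return Factor with levels [bias_states].
#' @export
bias_state <- function(q, sign, alpha = 0.05) {
  if (anyNA(q) || any(q < 0 | q > 1)) stop("q-values must lie in [0, 1]")
  bad <- q < alpha & sign == 0
  if (any(bad)) {
    stop(sum(bad), " pair(s) significant but with zero divergence sign; ",
         "inconsistent inputs")
  }
  st <- ifelse(q >= alpha, "A_eq_C", ifelse(sign > 0, "A_gt_C", "A_lt_C"))
  factor(st, levels = bias_states)
}

#' Assign transmission patterns to parental/progeny state pairs
#'
#' @param parental,progeny Bias-state vectors (factors or characters with
#'   values in [bias_states]), aligned by pair.
#' @param pair_id Optional pair identifiers.
#' @return Data frame: `pair_id`, `parental`, `progeny`, `pattern` (I-IX),
#'   `group` (A/B/C).
#' @export
assign_pattern <- function(parental, progeny, pair_id = NULL) {
  parental <- as.character(parental)
  progeny <- as.character(progeny)
  if (length(parental) != length(progeny)) {
    stop("parental and progeny states must align")
  }
  if (!all(parental %in% bias_states) || !all(progeny %in% bias_states)) {
    stop("states must be one of: ", paste(bias_states, collapse = ", "))
  }
  key <- paste(parental, progeny)
  tab_key <- paste(transmission_patterns$parental, transmission_patterns$progeny)
  idx <- match(key, tab_key)
  data.frame(pair_id = pair_id %||% seq_along(parental),
             parental = factor(parental, levels = bias_states),
             progeny = factor(progeny, levels = bias_states),
             pattern = factor(transmission_patterns$pattern[idx],
                              levels = transmission_patterns$pattern),
             group = factor(transmission_patterns$group[idx],
                            levels = c("A", "B", "C")),
             stringsAsFactors = FALSE)
}

#' Summarize transmission records
#'
#' @param records Output of [assign_pattern()].
#' @return List with `grid` (3 x 3 parental-by-progeny count table),
#'   `patterns` (count and proportion per pattern), `groups` (per group),
#'   and `maintenance_rate`: among pairs balanced in the parents
#'   (`A_eq_C`), the fraction whose progeny state is also balanced (`NA`
#'   when no pair is parentally balanced).
#' @export
transmission_summary <- function(records) {
  if (nrow(records) == 0) stop("no transmission records to summarize")
  grid <- table(parental = factor(records$parental, levels = bias_states),
                progeny = factor(records$progeny, levels = bias_states))
  pt <- table(factor(records$pattern, levels = transmission_patterns$pattern))
  gt <- table(factor(records$group, levels = c("A", "B", "C")))
  par_eq <- records$parental == "A_eq_C"
  maintenance <- if (any(par_eq)) {
    mean(records$progeny[par_eq] == "A_eq_C")
  } else {
    NA_real_
  }
  list(grid = grid,
       patterns = data.frame(pattern = names(pt), n = as.integer(pt),
                             proportion = as.numeric(pt) / sum(pt),
                             stringsAsFactors = FALSE),
       groups = data.frame(group = names(gt), n = as.integer(gt),
                           proportion = as.numeric(gt) / sum(gt),
                           stringsAsFactors = FALSE),
       maintenance_rate = maintenance)
}
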