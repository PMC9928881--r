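#' Actionable driver oncogene labels
#'
#' The seven genes on the NGS panel, in canonical order. "NONE" marks
#' driver-negative patients in cohort tables.
#' @export
ado_genes <- function() {
  c("EGFR", "ALK", "ROS1", "BRAF", "MET", "RET", "NTRK")
}

# group sums fixed by the study design; per-gene split is configurable
.default_split <- c(EGFR = 0.150, ALK = 0.040, ROS1 = 0.026, BRAF = 0.022,
                    MET = 0.030, RET = 0.020, NTRK = 0.005)

#' Per-gene driver prevalence table
#'
#' Validated mapping from gene label to population prevalence. The two
#' group totals are the study's ground truth: EGFR + ALK (detectable by
#' single-gene testing) must equal `sgt_total` and all seven genes must
#' equal `panel_total`; the per-gene split within those sums is
#' configurable.
#'
#' @param entries Named numeric vector of prevalences over [ado_genes()].
#'   The default split sums to the required group totals.
#' @param sgt_total Required EGFR + ALK sum (default 0.19).
#' @param panel_total Required seven-gene sum (default 0.293).
#' @param tol Tolerance on the group-sum checks.
#' @return An object of class `prevalence_table` (a named numeric vector).
#' @examples
#' prevalence_table()
#' @export
prevalence_table <- function(entries = .default_split,
                             sgt_total = 0.19, panel_total = 0.293,
                             tol = 1e-9) {
  genes <- ado_genes()
  if (!is.numeric(entries) || is.null(names(entries)))
    stop("prevalences must be a named numeric vector")
  unknown <- setdiff(names(entries), genes)
  if (length(unknown))
    stop("unknown gene label(s): ", paste(unknown, collapse = ", "))
  p <- stats::setNames(numeric(length(genes)), genes)
  p[names(entries)] <- entries
  if (any(p < 0 | p > 1))
    stop("each prevalence must lie in [0, 1]")
  if (sum(p) > 1 + tol)
    stop("prevalences sum to ", format(sum(p)),
         " > 1; no driver-negative remainder left")
  if (abs(sum(p[c("EGFR", "ALK")]) - sgt_total) > tol)
    stop("EGFR + ALK prevalence is ", format(sum(p[c("EGFR", "ALK")])),
         " but the single-gene-detectable total must be ", sgt_total)
  if (abs(sum(p) - panel_total) > tol)
    stop("seven-gene prevalence sum is ", format(sum(p)),
         " but the panel total must be ", panel_total)
  structure(p, class = c("prevalence_table", "numeric"))
}

#' Generate a synthetic patient cohort
#'
#' One categorical draw per patient over the seven driver genes and the
#' driver-negative remainder; drivers are mutually exclusive.
#'
#' @param n Cohort size (>= 0); the study default is 89,000 newly
#'   diagnosed advanced nonsquamous NSCLC patients.
#' @param prevalences A [prevalence_table()].
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @return A data.frame with columns `patient_id` and `driver_gene`
#'   (factor over the gene labels plus "NONE").
#' @examples
#' head(generate_cohort(100, prevalence_table(), seed = 1))
#' @export
generate_cohort <- function(n, prevalences = prevalence_table(), seed = NULL) {
  stopifnot(inherits(prevalences, "prevalence_table"),
            is.numeric(n), length(n) == 1L, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  levs <- c(ado_genes(), "NONE")
  prob <- c(as.numeric(prevalences), 1 - sum(prevalences))
  gene <- if (n == 0) integer(0) else
    sample.int(length(levs), size = n, replace = TRUE, prob = prob)
  data.frame(
    patient_id = seq_len(n),
    driver_gene = factor(levs[gene], levels = levs)
  )
}

#' Expected per-gene patient counts
#'
#' Deterministic expectation of [generate_cohort()]: n * p per gene with
#' the driver-negative remainder absorbing the balance, so the counts sum
#' to `n` exactly.
#'
#' @inheritParams generate_cohort
#' @return Named numeric vector over [ado_genes()] plus "NONE".
#' @export
expected_counts <- function(n, prevalences = prevalence_table()) {
  stopifnot(inherits(prevalences, "prevalence_table"),
            is.numeric(n), length(n) == 1L, n >= 0)
  counts <- n * as.numeric(prevalences)
  names(counts) <- names(prevalences)
  c(counts, NONE = n - sum(counts))
}
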