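#' Population testing mix
#'
#' Partition of the population into untested patients, patients tested by
#' single-gene testing (SGT) and patients tested by a multigene NGS panel.
#' The study holds the untested share at 20% and sweeps the SGT/NGS split
#' of the remaining 80%; the default mix (65% SGT, 15% NGS) reflects
#' practice at study conception.
#'
#' @param untested Fraction receiving no testing (default 0.20).
#' @param sgt Fraction tested by SGT (default 0.65).
#' @param ngs Fraction tested by NGS (default 0.15).
#' @return An object of class `testing_mix`.
#' @export
testing_mix <- function(untested = 0.20, sgt = 0.65, ngs = 0.15) {
  f <- c(untested = untested, sgt = sgt, ngs = ngs)
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("testing mix fractions must each lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-12)
    stop("testing mix fractions sum to ", format(sum(f)),
         "; they must sum to 1")
  structure(as.list(f), class = "testing_mix")
}

#' Gene panels for the two testing modalities
#'
#' SGT assays EGFR and ALK only; the NGS panel covers all seven
#' actionable driver oncogenes.
#'
#' @param name Panel label, `"SGT"` or `"NGS"`.
#' @param genes Character vector of covered gene labels.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, is.character(genes))
  unknown <- setdiff(genes, ado_genes())
  if (length(unknown))
    stop("unknown gene label(s) in panel: ", paste(unknown, collapse = ", "))
  structure(list(name = name, genes = unique(genes)), class = "gene_panel")
}

#' @rdname gene_panel
#' @export
sgt_panel <- function() gene_panel("SGT", c("EGFR", "ALK"))

#' @rdname gene_panel
#' @export
ngs_panel <- function() gene_panel("NGS", ado_genes())

#' @rdname gene_panel
#' @export
default_panels <- function() list(SGT = sgt_panel(), NGS = ngs_panel())

#' Test performance characteristics
#'
#' The study assumes perfect assays; sensitivity and specificity below 1
#' are supported as an extension.
#'
#' @param sensitivity Probability a covered driver is called (default 1).
#' @param specificity Probability a driver-negative patient is not
#'   falsely called (default 1).
#' @return An object of class `test_performance`.
#' @export
test_performance <- function(sensitivity = 1, specificity = 1) {
  p <- c(sensitivity = sensitivity, specificity = specificity)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  structure(as.list(p), class = "test_performance")
}

#' Assign patients to testing modalities
#'
#' Independent categorical assignment with the mix probabilities;
#' assignment does not depend on driver status (testing eligibility is
#' assumed independent of tumour biology).
#'
#' @param cohort A cohort data.frame from [generate_cohort()].
#' @param mix A [testing_mix()].
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @return The cohort with an `assigned_test` factor column
#'   (NONE / SGT / NGS) appended.
#' @export
allocate_tests <- function(cohort, mix = testing_mix(), seed = NULL) {
  stopifnot(is.data.frame(cohort), inherits(mix, "testing_mix"))
  if (!is.null(seed)) set.seed(seed)
  levs <- c("NONE", "SGT", "NGS")
  prob <- c(mix$untested, mix$sgt, mix$ngs)
  n <- nrow(cohort)
  idx <- if (n == 0) integer(0) else
    sample.int(3L, size = n, replace = TRUE, prob = prob)
  cohort$assigned_test <- factor(levs[idx], levels = levs)
  cohort
}

#' Determine biomarker detection
#'
#' A tested patient's driver is detected with probability `sensitivity`
#' when the driver gene is on the assigned panel. With specificity below
#' one, driver-negative tested patients receive a false-positive call
#' with probability 1 - specificity, attributed to a uniformly random
#' in-panel gene (an extension; unreachable at the default perfect
#' specificity). Untested patients are never detected.
#'
#' @param cohort Cohort with `assigned_test` populated.
#' @param panels Named list of [gene_panel()]s as from [default_panels()].
#' @param performance A [test_performance()].
#' @param seed Optional integer seed; `NULL` continues the current stream.
#'   Unused at the default perfect performance.
#' @return The cohort with logical `detected` and character
#'   `detected_gene` (NA when nothing is called) columns appended.
#' @export
detect <- function(cohort, panels = default_panels(),
                   performance = test_performance(), seed = NULL) {
  stopifnot(is.data.frame(cohort), inherits(performance, "test_performance"))
  if (is.null(cohort$assigned_test))
    stop("detect: cohort must have assigned_test populated (run allocate_tests first)")
  for (p in panels) stopifnot(inherits(p, "gene_panel"))
  if (!is.null(seed)) set.seed(seed)
  panel_genes <- lapply(panels, `[[`, "genes")
  names(panel_genes) <- vapply(panels, `[[`, character(1), "name")

  gene <- as.character(cohort$driver_gene)
  test <- as.character(cohort$assigned_test)
  n <- nrow(cohort)
  in_panel <- logical(n)
  for (nm in names(panel_genes)) {
    sel <- test == nm
    in_panel[sel] <- gene[sel] %in% panel_genes[[nm]]
  }
  detected <- logical(n)
  detected_gene <- rep(NA_character_, n)

  true_pos <- in_panel & gene != "NONE"
  if (performance$sensitivity >= 1) {
    detected[true_pos] <- TRUE
  } else {
    detected[true_pos] <- stats::runif(sum(true_pos)) < performance$sensitivity
  }
  detected_gene[detected] <- gene[detected]

  if (performance$specificity < 1) {
    neg_tested <- gene == "NONE" & test != "NONE"
    fp <- neg_tested & stats::runif(n) < (1 - performance$specificity)
    for (nm in names(panel_genes)) {
      sel <- fp & test == nm
      if (any(sel)) {
        detected[sel] <- TRUE
        detected_gene[sel] <- sample(panel_genes[[nm]], sum(sel), replace = TRUE)
      }
    }
  }
  cohort$detected <- detected
  cohort$detected_gene <- detected_gene
  cohort
}

#' Closed-form identified fraction
#'
#' Exact expected fraction of the whole population whose driver oncogene
#' is identified: sum over genes of p_g times the probability of being
#' assigned a panel covering g times sensitivity. No sampling involved.
#'
#' @param mix A [testing_mix()].
#' @param prevalences A [prevalence_table()].
#' @param panels Named list of panels as from [default_panels()].
#' @param performance A [test_performance()].
#' @return A probability.
#' @examples
#' # SGT-only testing identifies 15.2% of the population
#' identified_fraction_analytic(testing_mix(0.20, 0.80, 0.00))
#' @export
identified_fraction_analytic <- function(mix = testing_mix(),
                                         prevalences = prevalence_table(),
                                         panels = default_panels(),
                                         performance = test_performance()) {
  stopifnot(inherits(mix, "testing_mix"),
            inherits(prevalences, "prevalence_table"),
            inherits(performance, "test_performance"))
  panel_genes <- lapply(panels, `[[`, "genes")
  names(panel_genes) <- vapply(panels, `[[`, character(1), "name")
  assign_prob <- c(SGT = mix$sgt, NGS = mix$ngs)
  total <- 0
  for (g in names(prevalences)) {
    p_test <- sum(vapply(names(panel_genes), function(nm) {
      if (g %in% panel_genes[[nm]]) assign_prob[[nm]] else 0
    }, numeric(1)))
    total <- total + prevalences[[g]] * p_test * performance$sensitivity
  }
  as.numeric(total)
}
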