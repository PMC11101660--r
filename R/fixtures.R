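#' Built-in five-gene female breast cancer panel
#'
#' Carrier prevalences and cumulative lifetime penetrances for deleterious
#' variants in ATM, BRCA1, BRCA2, CHEK2 (1100delC only) and PALB2, with
#' precisions of 10,000 for BRCA1/BRCA2 (well-studied, tight uncertainty)
#' and 100 for the other three (wider uncertainty). All test disutilities
#' are 0. Prevalences are stored exactly as published; if they are allele
#' frequencies in your source, convert with
#' [allele_freq_to_carrier_prevalence()].
#'
#' @param high_precision_variant If `TRUE`, substitute the three-decimal
#'   penetrances implied by the published range (BRCA1 0.732, CHEK2 0.195)
#'   for the two-decimal display values. Threshold-table rounding for CHEK2
#'   (4.1 rather than 4.3) is only reproducible with this variant.
#' @return A [gene_panel()] with five pairs and no panel-level
#'   disutilities.
#' @examples
#' breast_cancer_panel()
#' @export
breast_cancer_panel <- function(high_precision_variant = FALSE) {
  pen <- if (high_precision_variant) {
    c(0.35, 0.732, 0.72, 0.195, 0.38)
  } else {
    c(0.35, 0.73, 0.72, 0.19, 0.38)
  }
  pairs <- data.frame(
    disease_id = rep("female_breast_cancer", 5),
    gene_id = c("ATM", "BRCA1", "BRCA2", "CHEK2", "PALB2"),
    carrier_prevalence = c(0.0019, 0.00058, 0.00068, 0.0026, 0.00057),
    penetrance = pen,
    precision = c(100, 10000, 10000, 100, 100),
    test_disutility = 0,
    stringsAsFactors = FALSE
  )
  gene_panel(pairs)
}

#' Generate a random synthetic panel
#'
#' Reproducible random panels for property tests and simulation studies.
#' Default ranges mirror values seen in clinical practice for rare
#' monogenic conditions: carrier prevalences 0.001-0.004, penetrances
#' 0.2-0.99, precisions drawn from {10, 100, 1000, 10000}.
#'
#' @param n_pairs Number of (disease, gene) pairs (0 gives an empty panel).
#' @param prevalence_range Length-2 range for carrier prevalences.
#' @param penetrance_range Length-2 range for penetrances.
#' @param precision_choices Non-empty set of precision values to sample.
#' @param seed Integer seed (required).
#' @param disutilities Optional shared [disutility_spec()] to attach.
#' @return A [gene_panel()] with genes labelled `GENE1..GENEn` for disease
#'   `"disease"`.
#' @export
synthetic_panel <- function(n_pairs,
                            prevalence_range = c(0.001, 0.004),
                            penetrance_range = c(0.2, 0.99),
                            precision_choices = c(10, 100, 1000, 10000),
                            seed, disutilities = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(prevalence_range) != 2 || length(penetrance_range) != 2 ||
      length(precision_choices) < 1) {
    stop("empty parameter range", call. = FALSE)
  }
  if (n_pairs == 0) {
    empty <- data.frame(disease_id = character(0), gene_id = character(0),
                        carrier_prevalence = numeric(0),
                        penetrance = numeric(0), precision = numeric(0),
                        test_disutility = numeric(0),
                        stringsAsFactors = FALSE)
    return(gene_panel(empty, disutilities = disutilities))
  }
  pairs <- NULL
  with_preserved_rng({
    set.seed(as.integer(seed))
    pairs <- data.frame(
      disease_id = rep("disease", n_pairs),
      gene_id = paste0("GENE", seq_len(n_pairs)),
      carrier_prevalence = stats::runif(n_pairs, prevalence_range[1],
                                        prevalence_range[2]),
      penetrance = stats::runif(n_pairs, penetrance_range[1],
                                penetrance_range[2]),
      precision = sample(precision_choices, n_pairs, replace = TRUE),
      test_disutility = 0,
      stringsAsFactors = FALSE
    )
  })
  gene_panel(pairs, disutilities = disutilities)
}
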