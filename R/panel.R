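#' Construct a (disease, gene) pair
#'
#' The atomic unit of a screening panel: one disease--gene combination with
#' its carrier prevalence \eqn{\Pr(G=1)}, lifetime penetrance
#' \eqn{p = \Pr(D=1 \mid G=1)}, a precision parameter \eqn{n} (the effective
#' trial size behind the penetrance estimate; it parameterises the Beta
#' uncertainty distribution with \eqn{\alpha = np}, \eqn{\beta = n(1-p)})
#' and an optional per-test disutility \eqn{K}.
#'
#' `K` enters the net utility additively, so a harm from testing itself must
#' be supplied as a negative number; the default 0 means the act of testing
#' is utility-neutral.
#'
#' @param disease_id,gene_id Non-empty character labels.
#' @param carrier_prevalence Probability of carrying a deleterious variant,
#'   in \[0, 1\].
#' @param penetrance Probability a carrier develops the disease over a
#'   lifetime, in \[0, 1\].
#' @param precision Positive effective trial size for the penetrance
#'   estimate's uncertainty distribution.
#' @param test_disutility Additive utility contribution of performing the
#'   test itself (negative for a harm). Default 0.
#' @return A one-row `data.frame` of class `gene_disease_pair`.
#' @seealso [gene_panel()], [net_utility_pair()]
#' @examples
#' gene_disease_pair("breast_cancer", "ATM", 0.0019, 0.35, 100)
#' @export
gene_disease_pair <- function(disease_id, gene_id, carrier_prevalence,
                              penetrance, precision, test_disutility = 0) {
  check_label(disease_id, "disease_id")
  check_label(gene_id, "gene_id")
  check_probability(carrier_prevalence, "carrier_prevalence")
  check_probability(penetrance, "penetrance")
  check_positive(precision, "precision")
  check_number(test_disutility, "test_disutility")
  pair <- data.frame(
    disease_id = disease_id, gene_id = gene_id,
    carrier_prevalence = carrier_prevalence, penetrance = penetrance,
    precision = precision, test_disutility = test_disutility,
    stringsAsFactors = FALSE
  )
  class(pair) <- c("gene_disease_pair", "data.frame")
  pair
}

#' Specify the two outcome-misalignment disutilities
#'
#' @param delta_gpos_dneg Strictly positive disutility of testing positive
#'   but never developing the disease (G+D-): unnecessary surveillance,
#'   overtreatment, anxiety.
#' @param delta_gneg_dpos Strictly positive disutility of testing negative
#'   but developing the disease (G-D+): false reassurance, missed intensive
#'   intervention.
#' @return A list of class `disutility_spec`.
#' @examples
#' disutility_spec(delta_gpos_dneg = 1, delta_gneg_dpos = 2)
#' @export
disutility_spec <- function(delta_gpos_dneg, delta_gneg_dpos) {
  check_strictly_positive(delta_gpos_dneg, "delta_gpos_dneg")
  check_strictly_positive(delta_gneg_dpos, "delta_gneg_dpos")
  structure(
    list(delta_gpos_dneg = delta_gpos_dneg, delta_gneg_dpos = delta_gneg_dpos),
    class = "disutility_spec"
  )
}

#' Four-outcome utility specification
#'
#' The full utility parameterisation over the four (disease, test) outcomes.
#' The headline net-utility formula depends on these only through the two
#' differences (the disutilities), so this type mainly serves as the
#' self-check oracle for the reduced expressions. The stated ordering
#' assumptions are enforced: a concordant outcome is always preferred to its
#' discordant counterpart.
#'
#' @param c_gpos_dpos Utility of testing positive and developing the disease.
#' @param c_gneg_dneg Utility of testing negative and not developing it.
#' @param c_gpos_dneg Utility of testing positive but not developing it;
#'   must be `< c_gneg_dneg`.
#' @param c_gneg_dpos Utility of testing negative but developing it;
#'   must be `< c_gpos_dpos`.
#' @return A list of class `outcome_utilities` carrying the induced
#'   disutilities as attribute `deltas`.
#' @export
outcome_utilities <- function(c_gpos_dpos, c_gneg_dneg, c_gpos_dneg,
                              c_gneg_dpos) {
  for (nm in c("c_gpos_dpos", "c_gneg_dneg", "c_gpos_dneg", "c_gneg_dpos")) {
    check_strictly_positive(get(nm), nm)
  }
  if (c_gpos_dneg >= c_gneg_dneg) {
    stop("c_gpos_dneg must be < c_gneg_dneg (a true-negative outcome is preferred)",
         call. = FALSE)
  }
  if (c_gneg_dpos >= c_gpos_dpos) {
    stop("c_gneg_dpos must be < c_gpos_dpos (a forewarned case is preferred)",
         call. = FALSE)
  }
  u <- list(c_gpos_dpos = c_gpos_dpos, c_gneg_dneg = c_gneg_dneg,
            c_gpos_dneg = c_gpos_dneg, c_gneg_dpos = c_gneg_dpos)
  attr(u, "deltas") <- disutility_spec(
    delta_gpos_dneg = c_gneg_dneg - c_gpos_dneg,
    delta_gneg_dpos = c_gpos_dpos - c_gneg_dpos
  )
  class(u) <- "outcome_utilities"
  u
}

#' Assemble a screening panel
#'
#' A panel is an ordered collection of (disease, gene) pairs together with
#' disutility settings: either one shared [disutility_spec()] or per-pair
#' values carried in `delta_gpos_dneg` / `delta_gneg_dpos` columns of the
#' pair table (per-pair values override the shared spec).
#'
#' @param pairs A `data.frame` with columns `disease_id`, `gene_id`,
#'   `carrier_prevalence`, `penetrance`, `precision`, optionally
#'   `test_disutility` (default 0) and per-pair `delta_gpos_dneg`,
#'   `delta_gneg_dpos`. Typically built by row-binding [gene_disease_pair()]
#'   calls.
#' @param disutilities Optional shared [disutility_spec()].
#' @return An object of class `gene_panel`: a list with elements `pairs`
#'   (validated data.frame) and `disutilities`.
#' @examples
#' gene_panel(breast_cancer_panel()$pairs,
#'            disutility_spec(1, 2))
#' @export
gene_panel <- function(pairs, disutilities = NULL) {
  stopifnot(is.data.frame(pairs))
  required <- c("disease_id", "gene_id", "carrier_prevalence", "penetrance",
                "precision")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols) > 0) {
    stop("pairs is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(pairs$test_disutility)) pairs$test_disutility <- 0
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      where <- sprintf(" (record %d: %s/%s)", r,
                       as.character(pairs$disease_id[r]),
                       as.character(pairs$gene_id[r]))
      check_label(pairs$disease_id[r], paste0("disease_id", where))
      check_label(pairs$gene_id[r], paste0("gene_id", where))
      check_probability(pairs$carrier_prevalence[r],
                        paste0("carrier_prevalence", where))
      check_probability(pairs$penetrance[r], paste0("penetrance", where))
      check_positive(pairs$precision[r], paste0("precision", where))
      check_number(pairs$test_disutility[r], paste0("test_disutility", where))
    }
    key <- paste(pairs$disease_id, pairs$gene_id, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop("duplicate (disease_id, gene_id) pair: ",
           gsub("\r", "/", dup), call. = FALSE)
    }
  }
  if (!is.null(disutilities) && !inherits(disutilities, "disutility_spec")) {
    disutilities <- do.call(disutility_spec, as.list(disutilities))
  }
  structure(list(pairs = pairs, disutilities = disutilities),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d (disease, gene) pair(s)\n", nrow(x$pairs)))
  if (!is.null(x$disutilities)) {
    cat(sprintf("  shared disutilities: G+D- %.4g, G-D+ %.4g\n",
                x$disutilities$delta_gpos_dneg,
                x$disutilities$delta_gneg_dpos))
  }
  print(x$pairs, ...)
  invisible(x)
}

#' @export
print.disutility_spec <- function(x, ...) {
  cat(sprintf("<disutility_spec> G+D- %.6g, G-D+ %.6g\n",
              x$delta_gpos_dneg, x$delta_gneg_dpos))
  invisible(x)
}

# Resolve one disutility pair per panel record. Precedence: per-record
# columns, then the `d` argument, then the panel-level spec.
resolve_disutilities <- function(panel, d = NULL) {
  pairs <- panel$pairs
  n <- nrow(pairs)
  base <- if (!is.null(d)) d else panel$disutilities
  d0 <- rep(if (is.null(base)) NA_real_ else base$delta_gpos_dneg, n)
  d1 <- rep(if (is.null(base)) NA_real_ else base$delta_gneg_dpos, n)
  if (!is.null(pairs$delta_gpos_dneg)) {
    d0 <- ifelse(is.na(pairs$delta_gpos_dneg), d0, pairs$delta_gpos_dneg)
  }
  if (!is.null(pairs$delta_gneg_dpos)) {
    d1 <- ifelse(is.na(pairs$delta_gneg_dpos), d1, pairs$delta_gneg_dpos)
  }
  if (anyNA(d0) || anyNA(d1)) {
    stop("panel pair(s) without resolvable disutilities; supply `d` or a ",
         "panel-level disutility_spec", call. = FALSE)
  }
  if (any(d0 <= 0) || any(d1 <= 0)) {
    stop("disutilities must be strictly positive", call. = FALSE)
  }
  data.frame(delta_gpos_dneg = d0, delta_gneg_dpos = d1)
}

# shared disutilities required (aggregate threshold assumption)
shared_disutilities <- function(panel, d = NULL) {
  dd <- resolve_disutilities(panel, d)
  if (nrow(dd) == 0) return(NULL)
  if (length(unique(dd$delta_gpos_dneg)) > 1 ||
      length(unique(dd$delta_gneg_dpos)) > 1) {
    stop("per-pair disutilities differ; the aggregate threshold assumes ",
         "shared disutilities - use a sweep-based root finding over ",
         "aggregate_utility() instead", call. = FALSE)
  }
  disutility_spec(dd$delta_gpos_dneg[1], dd$delta_gneg_dpos[1])
}

pair_labels <- function(pairs) {
  if (length(unique(pairs$disease_id)) <= 1) as.character(pairs$gene_id)
  else paste(pairs$disease_id, pairs$gene_id, sep = ":")
}

## -- validation helpers -------------------------------------------------

check_label <- function(x, field) {
  if (length(x) != 1 || !is.character(as.character(x)) || is.na(x) ||
      !nzchar(as.character(x))) {
    stop(field, " must be a non-empty label", call. = FALSE)
  }
  invisible(x)
}

check_number <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || !is.finite(x)) {
    stop(field, " must be a finite number", call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, field) {
  check_number(x, field)
  if (x < 0 || x > 1) stop(field, " must be in [0, 1]", call. = FALSE)
  invisible(x)
}

check_positive <- function(x, field) {
  check_number(x, field)
  if (x <= 0) stop(field, " must be > 0", call. = FALSE)
  invisible(x)
}

check_strictly_positive <- check_positive

# coerce a one-row data.frame / list into canonical pair fields
as_pair_fields <- function(pair) {
  if (inherits(pair, "gene_panel")) {
    if (nrow(pair$pairs) != 1) stop("expected a single pair", call. = FALSE)
    pair <- pair$pairs
  }
  if (is.data.frame(pair)) {
    if (nrow(pair) != 1) stop("expected a single pair", call. = FALSE)
    pair <- as.list(pair)
  }
  if (is.null(pair$test_disutility)) pair$test_disutility <- 0
  check_probability(pair$carrier_prevalence, "carrier_prevalence")
  check_probability(pair$penetrance, "penetrance")
  if (!is.null(pair$precision)) check_positive(pair$precision, "precision")
  check_number(pair$test_disutility, "test_disutility")
  pair
}
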