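#' Hybridization propensity
#'
#' The realized percentage of all possible pairwise hybrid combinations in a
#' group of `n` nonhybrid species:
#' \deqn{100 \cdot H / \{n(n-1)/2\}}
#' Because hybrid counts are summed across floras while the denominator uses
#' the summed species count, genus-level values can exceed 100.
#'
#' @param H Hybrid count (half-integers allowed; \eqn{\ge 0}).
#' @param n Nonhybrid species count (\eqn{\ge 2}).
#' @return Propensity in percent. Vectorized over `H` and `n`.
#' @seealso [hybrid_ratio()]
#' @export
#' @examples
#' hybridization_propensity(3, 5) # 30
hybridization_propensity <- function(H, n) {
  stopifnot(is.numeric(H), is.numeric(n))
  if (any(H < 0)) stop("hybrid count H must be nonnegative")
  if (any(n < 2)) {
    stop("hybridization propensity is undefined for n < 2 ",
         "(no species pair exists); such groups must be excluded upstream")
  }
  100 * H / (n * (n - 1) / 2)
}

#' Hybrid ratio
#'
#' Number of hybrid combinations relative to the number of nonhybrid species,
#' `H / n`. The denominator corrects for opportunity: more nonhybrid species
#' mean more chances to form hybrids.
#'
#' @inheritParams hybridization_propensity
#' @param n Nonhybrid species count (\eqn{\ge 1}).
#' @return Dimensionless ratio. Vectorized.
#' @export
#' @examples
#' hybrid_ratio(1.5, 10) # 0.15
hybrid_ratio <- function(H, n) {
  stopifnot(is.numeric(H), is.numeric(n))
  if (any(H < 0)) stop("hybrid count H must be nonnegative")
  if (any(n < 1)) stop("hybrid ratio is undefined for n < 1")
  H / n
}

#' Estimate hybrid count for unspecified "multiple hybrids" records
#'
#' Some floras state that a group produces multiple hybrids without giving
#' numbers or parents. Such records are resolved to the larger of 2 hybrids or
#' 20% of the species present.
#'
#' @param n Species count in the record (\eqn{\ge 1}).
#' @return Estimated hybrid count, `max(2, 0.2 * n)`. Vectorized.
#' @export
resolve_unspecified_hybrids <- function(n) {
  stopifnot(is.numeric(n))
  if (any(n < 1)) stop("species count must be >= 1")
  pmax(2, 0.2 * n)
}

#' Validate a set of per-flora hybridization records
#'
#' Checks the column contract of a flora record table: one row per
#' (genus, flora) with nonnegative counts, intergeneric contributions in steps
#' of 0.5, and a logical unspecified-multiple flag.
#'
#' @param records Data frame with columns `genus`, `family`, `flora`,
#'   `n_nonhybrid`, `n_intrageneric_hybrids`, `n_intergeneric_hybrid_halves`,
#'   `unspecified_multiple`.
#' @return The validated data frame, invisibly classed `flora_records`.
#' @export
validate_flora_records <- function(records) {
  required <- c("genus", "family", "flora", "n_nonhybrid",
                "n_intrageneric_hybrids", "n_intergeneric_hybrid_halves",
                "unspecified_multiple")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("flora records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records$unspecified_multiple <- as.logical(records$unspecified_multiple)
  num_cols <- c("n_nonhybrid", "n_intrageneric_hybrids",
                "n_intergeneric_hybrid_halves")
  for (cl in num_cols) {
    v <- records[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop("column ", cl, " must be numeric, nonnegative and complete")
    }
  }
  halves <- records$n_intergeneric_hybrid_halves
  if (any(abs(halves * 2 - round(halves * 2)) > 1e-9)) {
    stop("n_intergeneric_hybrid_halves must come in steps of 0.5")
  }
  key <- paste(records$genus, records$flora, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop("duplicate (genus, flora) records: ",
         paste(unique(paste(dup$genus, dup$flora)), collapse = "; "))
  }
  class(records) <- unique(c("flora_records", class(records)))
  invisible(records)
}

#' Read per-flora hybridization records from CSV
#'
#' @param path CSV with header `genus,family,flora,n_nonhybrid,`
#'   `n_intrageneric_hybrids,n_intergeneric_hybrid_halves,unspecified_multiple`.
#' @return Validated `flora_records` data frame.
#' @export
read_flora_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_flora_records(df)
}

# Resolve unspecified-multiple flags on a record table: the record's
# intrageneric hybrid count becomes max(stated, max(2, 0.2 n)).
resolve_flora_records <- function(records) {
  idx <- which(records$unspecified_multiple & records$n_nonhybrid >= 1)
  if (length(idx) > 0) {
    est <- resolve_unspecified_hybrids(records$n_nonhybrid[idx])
    records$n_intrageneric_hybrids[idx] <-
      pmax(records$n_intrageneric_hybrids[idx], est)
  }
  records
}

# Per-record hybrid count: intrageneric hybrids plus half of each
# intergeneric half-assignment.
record_hybrid_count <- function(records) {
  records$n_intrageneric_hybrids + 0.5 * records$n_intergeneric_hybrid_halves
}

#' Aggregate per-flora records to genus-level hybridization summaries
#'
#' Sums nonhybrid species and hybrid counts across floras for each genus (no
#' attempt is made to avoid double counting of the same parental pair observed
#' in different regions: a pair seen in two floras contributes two hybrids),
#' resolves unspecified-multiple records first, and computes both metrics from
#' the summed counts. Genera whose summed `n` is below the metric's domain get
#' `NA` for that metric.
#'
#' @param records Validated `flora_records` table (see
#'   [validate_flora_records()]).
#' @param distinct_n If `TRUE`, use the maximum per-flora species count as `n`
#'   instead of the across-flora sum (an approximation to the number of
#'   distinct species). Default `FALSE`: literal summation.
#' @return Data frame, one row per genus, columns `taxon`, `level`, `family`,
#'   `n`, `H`, `n_floras`, `propensity`, `ratio`.
#' @export
aggregate_genus <- function(records, distinct_n = FALSE) {
  records <- validate_flora_records(records)
  records <- resolve_flora_records(records)
  records$H_rec <- record_hybrid_count(records)

  fam <- tapply(records$family, records$genus, function(f) f[[1]])
  n_fun <- if (distinct_n) max else sum
  n <- tapply(records$n_nonhybrid, records$genus, n_fun)
  H <- tapply(records$H_rec, records$genus, sum)
  n_floras <- tapply(records$flora, records$genus, function(x) length(unique(x)))

  genera <- names(n)
  out <- data.frame(
    taxon = genera,
    level = "genus",
    family = as.character(fam[genera]),
    n = as.numeric(n[genera]),
    H = as.numeric(H[genera]),
    n_floras = as.integer(n_floras[genera]),
    stringsAsFactors = FALSE
  )
  out$propensity <- ifelse(out$n >= 2,
                           100 * out$H / (out$n * (out$n - 1) / 2), NA_real_)
  out$ratio <- ifelse(out$n >= 1, out$H / out$n, NA_real_)
  rownames(out) <- NULL
  out
}

#' Exclude genera with no chance of hybridization
#'
#' Removes genera observed with a single nonhybrid species in a single flora
#' and no hybrids (a lone species cannot form an intrageneric hybrid), plus any
#' caller-specified unplaceable taxa (e.g. taxa missing from the phylogeny).
#'
#' @param summaries Genus-level summaries from [aggregate_genus()].
#' @param records The record table the summaries were computed from.
#' @param drop_taxa Character vector of additional taxa to drop.
#' @return Filtered summaries.
#' @export
apply_exclusions <- function(summaries, records, drop_taxa = character()) {
  single <- summaries$n_floras == 1 & summaries$n == 1 & summaries$H == 0
  keep <- !single & !(summaries$taxon %in% drop_taxa)
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate genus summaries to the family level
#'
#' Family metrics are means of the component-genus metrics weighted by each
#' genus's nonhybrid species count; family `n` and `H` are sums. Genera with an
#' undefined metric (n below the metric's domain) are omitted from that
#' metric's weighted mean.
#'
#' @param genus_summaries Output of [aggregate_genus()] (after exclusions).
#' @param genus_to_family Optional named character vector mapping genus to
#'   family; defaults to the `family` column of `genus_summaries`.
#' @return Data frame, one row per family: `taxon`, `level`, `n`, `H`,
#'   `n_genera`, `propensity`, `ratio`.
#' @export
aggregate_family <- function(genus_summaries, genus_to_family = NULL) {
  gs <- genus_summaries
  if (is.null(genus_to_family)) {
    fam <- gs$family
  } else {
    fam <- unname(genus_to_family[gs$taxon])
    if (anyNA(fam)) {
      bad <- gs$taxon[is.na(fam)]
      stop("genera with no family mapping: ", paste(bad, collapse = ", "))
    }
  }
  families <- sort(unique(fam))
  f <- factor(fam, levels = families)
  out <- data.frame(
    taxon = families,
    level = "family",
    n = as.numeric(tapply(gs$n, f, sum)),
    H = as.numeric(tapply(gs$H, f, sum)),
    n_genera = as.integer(tapply(gs$taxon, f, length)),
    stringsAsFactors = FALSE
  )
  prop <- rep(NA_real_, length(families))
  rat <- rep(NA_real_, length(families))
  for (i in seq_along(families)) {
    sel <- which(fam == families[i])
    p <- gs$propensity[sel]; r <- gs$ratio[sel]; w <- gs$n[sel]
    prop[i] <- if (any(!is.na(p))) sum(p * w, na.rm = TRUE) / sum(w[!is.na(p)]) else NA_real_
    rat[i]  <- if (any(!is.na(r))) sum(r * w, na.rm = TRUE) / sum(w[!is.na(r)]) else NA_real_
  }
  out$propensity <- prop
  out$ratio <- rat
  rownames(out) <- NULL
  out
}

#' Log-transform hybridization metrics
#'
#' Adds `log_propensity = ln(propensity + offset_propensity)` and
#' `log_ratio = ln(ratio + offset_ratio)` columns. Both metrics include exact
#' zeros, so a positive offset is required; the default of 1 maps zero to zero
#' and preserves ordering.
#'
#' @param summaries Genus- or family-level summary table with `propensity` and
#'   `ratio` columns.
#' @param offset_propensity,offset_ratio Nonnegative offsets added before the
#'   natural log.
#' @return `summaries` with `log_propensity` and `log_ratio` columns.
#' @export
log_transform_metrics <- function(summaries, offset_propensity = 1,
                                  offset_ratio = 1) {
  check_offset <- function(x, offset, what) {
    if (any(x[!is.na(x)] + offset <= 0)) {
      stop("log of nonpositive ", what,
           ": supply a positive offset when the metric includes zeros")
    }
  }
  check_offset(summaries$propensity, offset_propensity, "propensity")
  check_offset(summaries$ratio, offset_ratio, "ratio")
  summaries$log_propensity <- log(summaries$propensity + offset_propensity)
  summaries$log_ratio <- log(summaries$ratio + offset_ratio)
  summaries
}

#' Write a summary table to CSV
#'
#' @param summaries Summary data frame.
#' @param path Output CSV path.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
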