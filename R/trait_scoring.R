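#' Default trait scoring vocabulary
#'
#' The 0 / 0.5 / 1 coding schemes for the categorical traits, oriented as in
#' the analysis: herbaceous->woody, abiotic->biotic pollination,
#' actinomorphic->zygomorphic symmetry, asexual->sexual breeding,
#' vegetative->generative reproduction. Intermediate, mixed or combined states
#' score 0.5. Users can extend any trait's map with synonyms (e.g.
#' `"wind" = 0` under `pollination_syndrome`) via the `extra` argument.
#'
#' @param extra Named list of named numeric vectors merged over the defaults,
#'   one element per trait.
#' @return Named list of named numeric vectors (state -> score).
#' @export
default_trait_vocab <- function(extra = list()) {
  vocab <- list(
    woodiness = c(herbaceous = 0, either = 0.5, woody = 1),
    pollination_syndrome = c(abiotic = 0, both = 0.5, biotic = 1),
    floral_symmetry = c(actinomorphic = 0, both = 0.5, zygomorphic = 1),
    breeding_system = c(asexual = 0, both = 0.5, sexual = 1),
    reproductive_system = c(vegetative = 0, both = 0.5, generative = 1)
  )
  for (trait in names(extra)) {
    vocab[[trait]] <- c(extra[[trait]],
                        vocab[[trait]][setdiff(names(vocab[[trait]]),
                                               names(extra[[trait]]))])
  }
  vocab
}

#' Score a categorical trait state
#'
#' @param trait Trait name (a key of [default_trait_vocab()]).
#' @param raw_state Observed state label.
#' @param vocab Vocabulary from [default_trait_vocab()].
#' @return Score in {0, 0.5, 1}.
#' @export
#' @examples
#' score_categorical("pollination_syndrome", "abiotic") # 0
score_categorical <- function(trait, raw_state, vocab = default_trait_vocab()) {
  map <- vocab[[trait]]
  if (is.null(map)) stop("no vocabulary for trait '", trait, "'")
  s <- map[tolower(trimws(raw_state))]
  if (anyNA(s)) {
    bad <- unique(raw_state[is.na(s)])
    stop("unknown state(s) for trait '", trait, "': ",
         paste(bad, collapse = ", "))
  }
  unname(s)
}

#' Split a life-history state into fractional category weights
#'
#' Slash-joined compounds split unit mass equally among listed categories
#' ("annual/biennial" counts as 0.5 annual and 0.5 biennial). The perenniality
#' score attached to the result follows the intermediate coding: 0 when no
#' weight is on perennial, 1 when all of it is, 0.5 for any mixture (so
#' "annual/biennial/perennial" scores 0.5).
#'
#' @param raw_state Category label or slash-joined compound over
#'   annual/biennial/perennial.
#' @return List with `weights` (named numeric summing to 1) and
#'   `perenniality` (0, 0.5 or 1); `NA` perenniality for an empty state.
#' @export
split_life_history <- function(raw_state) {
  state <- tolower(trimws(raw_state))
  if (is.na(state) || !nzchar(state)) {
    return(list(weights = numeric(0), perenniality = NA_real_))
  }
  cats <- trimws(strsplit(state, "/", fixed = TRUE)[[1]])
  allowed <- c("annual", "biennial", "perennial")
  if (!all(cats %in% allowed)) {
    stop("unknown life-history categories: ",
         paste(setdiff(cats, allowed), collapse = ", "))
  }
  w <- rep(1 / length(cats), length(cats))
  names(w) <- cats
  pw <- sum(w[names(w) == "perennial"])
  per <- if (pw == 0) 0 else if (pw == 1) 1 else 0.5
  list(weights = w, perenniality = per)
}

#' Score an IUCN Red List category
#'
#' Numeric threat coding: LC = 0; NT and LR/nt = 0.5; LR/cd = 1; VU = 2;
#' EN = 3; CR = 4; EX and EW = 5.
#'
#' @param category Red List category label.
#' @return Score in \[0, 5\]. Vectorized.
#' @export
score_redlist <- function(category) {
  map <- c("LC" = 0, "NT" = 0.5, "LR/NT" = 0.5, "LR/CD" = 1,
           "VU" = 2, "EN" = 3, "CR" = 4, "EX" = 5, "EW" = 5)
  s <- map[toupper(trimws(category))]
  if (anyNA(s)) {
    stop("unknown Red List category: ",
         paste(unique(category[is.na(s)]), collapse = ", "))
  }
  unname(s)
}

#' Summarize genome sizes (C-values) for a taxon
#'
#' Order of operations: per-species mean over all ploidy-level variants, then
#' the taxon mean over species, log-transformed last. The coefficient of
#' variation is computed across the per-ploidy-level mean C-values pooled
#' within the taxon (a proxy for ploidy-driven genome-size variability).
#'
#' @param values Positive C-values in picograms.
#' @param species Species label per value.
#' @param ploidy Ploidy level per value (defaults to 1 variant per species).
#' @param cv_sd `"sample"` (n-1 denominator, default) or `"population"`.
#' @return List with `species_means`, `mean_c` (pg), `log_mean_c`, `cv`.
#' @export
summarize_c_values <- function(values, species, ploidy = NULL,
                               cv_sd = c("sample", "population")) {
  cv_sd <- match.arg(cv_sd)
  if (any(values <= 0)) stop("C-values must be positive (picograms)")
  if (is.null(ploidy)) ploidy <- rep(1L, length(values))
  stopifnot(length(species) == length(values), length(ploidy) == length(values))

  key <- paste(species, ploidy, sep = "\r")
  ploidy_means <- tapply(values, key, mean)           # per (species, ploidy)
  sp_of_key <- sub("\r.*$", "", names(ploidy_means))
  species_means <- tapply(as.numeric(ploidy_means), sp_of_key, mean)

  mean_c <- mean(species_means)
  pm <- as.numeric(ploidy_means)
  if (length(pm) < 2) {
    cv <- 0
  } else {
    s <- stats::sd(pm)
    if (cv_sd == "population") s <- s * sqrt((length(pm) - 1) / length(pm))
    cv <- s / mean(pm)
  }
  list(species_means = species_means, mean_c = mean_c,
       log_mean_c = log(mean_c), cv = cv)
}

#' Read species-level trait records from CSV
#'
#' @param path CSV with columns `species,genus,family,trait,raw_state` and
#'   optional `ploidy_level,value` (used by `c_value` rows).
#' @return Data frame of species trait records.
#' @export
read_trait_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("species", "genus", "family", "trait", "raw_state")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trait records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df
}

# Score one species record to a numeric value, or NA when unscorable.
score_species_record <- function(trait, raw_state, vocab) {
  if (is.na(raw_state) || !nzchar(trimws(as.character(raw_state)))) {
    return(NA_real_)
  }
  switch(trait,
    perenniality = split_life_history(raw_state)$perenniality,
    redlist = score_redlist(raw_state),
    agricultural = as.numeric(tolower(trimws(raw_state)) %in%
                                c("1", "crop", "yes", "true")),
    outcrossing_rate = {
      t <- as.numeric(raw_state)
      if (is.na(t) || t < 0 || t > 1) stop("outcrossing rate must be in [0,1]")
      t
    },
    score_categorical(trait, raw_state, vocab)
  )
}

#' Mean trait scores per taxon
#'
#' Species trait states are scored on the 0/0.5/1 (or Red List 0-5) scales and
#' averaged, unweighted, across all scored species in each genus or family
#' (family-level pooling is across species, equivalently genus means weighted
#' by species count). The agricultural score is the fraction of species listed
#' as crops. C-value rows (trait `"c_value"` with `value` and optional
#' `ploidy_level` columns) are summarized via [summarize_c_values()] into a
#' mean log C-value and a coefficient of variation. Traits with no scored
#' species in a taxon are `NA`, never zero.
#'
#' @param records Species trait records (see [read_trait_records()]).
#' @param level `"genus"` or `"family"`.
#' @param vocab Vocabulary for categorical traits.
#' @param cv_sd Passed to [summarize_c_values()].
#' @return Data frame: one row per taxon, one column per trait mean, plus
#'   `n_species_<trait>` counts of species scored.
#' @export
taxon_trait_means <- function(records, level = c("genus", "family"),
                              vocab = default_trait_vocab(),
                              cv_sd = "sample") {
  level <- match.arg(level)
  group <- records[[level]]
  taxa <- sort(unique(group))

  traits <- c("perenniality", "woodiness", "pollination_syndrome",
              "floral_symmetry", "outcrossing_rate", "breeding_system",
              "reproductive_system", "redlist", "agricultural")
  out <- data.frame(taxon = taxa, level = level, stringsAsFactors = FALSE)

  for (tr in traits) {
    sub <- records[records$trait == tr, , drop = FALSE]
    mean_col <- rep(NA_real_, length(taxa))
    n_col <- rep(0L, length(taxa))
    if (nrow(sub) > 0) {
      scores <- vapply(seq_len(nrow(sub)), function(i) {
        score_species_record(tr, sub$raw_state[i], vocab)
      }, numeric(1))
      ok <- !is.na(scores)
      if (any(ok)) {
        g <- sub[[level]][ok]
        m <- tapply(scores[ok], g, mean)
        cnt <- tapply(scores[ok], g, length)
        mean_col[match(names(m), taxa)] <- as.numeric(m)
        n_col[match(names(cnt), taxa)] <- as.integer(cnt)
      }
    }
    out[[tr]] <- mean_col
    out[[paste0("n_species_", tr)]] <- n_col
  }

  cv_rows <- records[records$trait == "c_value", , drop = FALSE]
  log_c <- rep(NA_real_, length(taxa))
  cv_c <- rep(NA_real_, length(taxa))
  n_c <- rep(0L, length(taxa))
  if (nrow(cv_rows) > 0) {
    if (!("value" %in% names(cv_rows))) {
      stop("c_value records require a 'value' column (picograms)")
    }
    pl <- if ("ploidy_level" %in% names(cv_rows)) cv_rows$ploidy_level else NULL
    for (tx in unique(cv_rows[[level]])) {
      sel <- cv_rows[[level]] == tx
      sm <- summarize_c_values(cv_rows$value[sel], cv_rows$species[sel],
                               if (is.null(pl)) NULL else pl[sel],
                               cv_sd = cv_sd)
      i <- match(tx, taxa)
      log_c[i] <- sm$log_mean_c
      cv_c[i] <- sm$cv
      n_c[i] <- length(sm$species_means)
    }
  }
  out$log_c_value <- log_c
  out$cv_c_value <- cv_c
  out$n_species_c_value <- n_c
  out
}
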