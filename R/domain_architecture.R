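# Domain-architecture classification from ranked profile-HMM hit tables.
#
# The three target models are COG2605 (kinase/FUK domain), PF07959
# (pyrophosphorylase/GFPP domain) and PRK13412 (full-length bifunctional
# FKP). Membership rules:
#   FUK set:  top model in {COG2605, PRK13412}, OR PF07959 together with
#             one of {COG2605, PRK13412} within the top two.
#   GFPP set: top model in {PF07959, PRK13412}, OR COG2605 together with
#             one of {PF07959, PRK13412} within the top two.
#   FKP set:  all of {COG2605, PF07959, PRK13412} within the top three.
# Each membership is then revoked when the sequence length falls below
# the per-dataset minimum or above the shared maximum.

TARGET_MODELS <- c(fuk = "COG2605", gfpp = "PF07959", fkp = "PRK13412")

#' Length-filter thresholds for architecture classification
#'
#' The standard minima are 333 residues for the FUK dataset, 406 for the
#' GFPP dataset and 739 for full-length FKPs, with a shared maximum of
#' 1745 residues. A stricter FKP minimum of 745 is in circulation for the
#' same datasets; pass `min_fkp = 745` to use it.
#'
#' @param min_fuk,min_gfpp,min_fkp per-dataset minimum lengths (residues).
#' @param max_len maximum length applied to all datasets.
#' @return a named list of thresholds.
#' @examples
#' arch_thresholds()
#' arch_thresholds(min_fkp = 745)
#' @export
arch_thresholds <- function(min_fuk = 333L, min_gfpp = 406L,
                            min_fkp = 739L, max_len = 1745L) {
  stopifnot(is_count(min_fuk), is_count(min_gfpp), is_count(min_fkp),
            is_count(max_len, positive = TRUE))
  list(min_fuk = min_fuk, min_gfpp = min_gfpp, min_fkp = min_fkp,
       max_len = max_len)
}

#' Read a profile-HMM hit table from TSV
#'
#' Expects a tab-separated file with header columns `query_id`,
#' `model_id` and `score`. Malformed score entries are reported with
#' their line numbers; missing columns raise a format error naming them.
#'
#' @param path TSV file path.
#' @return a data.frame (`query_id`, `model_id`, numeric `score`).
#' @export
read_hit_table <- function(path) {
  stopifnot(is_string(path))
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(c("query_id", "model_id", "score"), names(raw))
  if (length(missing))
    stop("hit table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty hit table: ", path)
    return(data.frame(query_id = character(0), model_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score) | !is.finite(score))
  if (length(bad))
    stop("hit table format error: non-numeric score on line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  out <- data.frame(query_id = raw$query_id, model_id = raw$model_id,
                    score = score, stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("query_id", "model_id")]))
    stop("hit table format error: duplicated (query_id, model_id) pairs")
  out
}

# normalize model identifiers: trim version suffixes ("PF07959.22" ->
# "PF07959") and compare case-insensitively
normalize_model_id <- function(model_id) {
  toupper(sub("\\.\\d+$", "", model_id))
}

#' Rank hit models per query
#'
#' Sorts each query's models by descending score, breaking ties
#' lexicographically by model identifier (matching hmmscan's primary
#' sort on bit score, with a deterministic tie-break).
#'
#' @param hits data.frame (`query_id`, `model_id`, `score`).
#' @return a named list mapping each query to its ordered character
#'   vector of (version-trimmed, uppercased) model identifiers.
#' @export
rank_models <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("query_id", "model_id", "score") %in% names(hits)))
  if (nrow(hits) == 0) return(stats::setNames(list(), character(0)))
  model <- normalize_model_id(hits$model_id)
  by_query <- split(data.frame(model = model, score = hits$score,
                               stringsAsFactors = FALSE),
                    hits$query_id)
  lapply(by_query, function(d) {
    d$model[order(-d$score, d$model, method = "radix")]
  })
}

#' Classify domain architectures from ranked model hits
#'
#' Applies the FUK/GFPP/FKP membership rules to each query's ranked
#' model list, then revokes memberships failing the length filters (see
#' [arch_thresholds()]). Queries with fewer than three hits can never be
#' in the FKP set; queries with no hits belong to no set.
#'
#' @param ranked named list of ordered model vectors, as produced by
#'   [rank_models()].
#' @param lengths named numeric vector (or data.frame with `id`/`query_id`
#'   and `length` columns) giving each query's sequence length; every
#'   ranked query must be present.
#' @param thresholds length thresholds, see [arch_thresholds()].
#' @return a data.frame of class `domain_calls` with one row per query:
#'   rule memberships before length filtering (`fuk_rule`, `gfpp_rule`,
#'   `fkp_rule`), length-pass flags, and the final `in_fuk_set`,
#'   `in_gfpp_set`, `in_fkp_set` memberships.
#' @examples
#' ranked <- list(q1 = c("PRK13412", "PF07959", "COG2605"))
#' classify_architecture(ranked, c(q1 = 900))
#' @export
classify_architecture <- function(ranked, lengths,
                                  thresholds = arch_thresholds()) {
  stopifnot(is.list(ranked))
  if (is.data.frame(lengths)) {
    idcol <- intersect(c("query_id", "id"), names(lengths))[1]
    if (is.na(idcol) || !"length" %in% names(lengths))
      stop("lengths data.frame needs an id column and a length column")
    lengths <- stats::setNames(lengths$length, lengths[[idcol]])
  }
  ids <- names(ranked)
  missing <- ids[!ids %in% names(lengths)]
  if (length(missing))
    stop("no length for query/queries: ", paste(missing, collapse = ", "))
  fuk_m <- TARGET_MODELS[["fuk"]]; gfpp_m <- TARGET_MODELS[["gfpp"]]
  fkp_m <- TARGET_MODELS[["fkp"]]
  one_row <- function(id) {
    mods <- ranked[[id]]
    top1 <- mods[seq_len(min(1L, length(mods)))]
    top2 <- mods[seq_len(min(2L, length(mods)))]
    top3 <- mods[seq_len(min(3L, length(mods)))]
    fuk_rule <- length(mods) > 0 &&
      (top1 %in% c(fuk_m, fkp_m) ||
         (gfpp_m %in% top2 && any(c(fuk_m, fkp_m) %in% top2)))
    gfpp_rule <- length(mods) > 0 &&
      (top1 %in% c(gfpp_m, fkp_m) ||
         (fuk_m %in% top2 && any(c(gfpp_m, fkp_m) %in% top2)))
    fkp_rule <- all(c(fuk_m, gfpp_m, fkp_m) %in% top3)
    len <- unname(lengths[[id]])
    fuk_len  <- len >= thresholds$min_fuk  && len <= thresholds$max_len
    gfpp_len <- len >= thresholds$min_gfpp && len <= thresholds$max_len
    fkp_len  <- len >= thresholds$min_fkp  && len <= thresholds$max_len
    data.frame(query_id = id, length = len,
               top_models = paste(top3, collapse = ","),
               fuk_rule = fuk_rule, gfpp_rule = gfpp_rule,
               fkp_rule = fkp_rule,
               fuk_length_pass = fuk_len, gfpp_length_pass = gfpp_len,
               fkp_length_pass = fkp_len,
               in_fuk_set = fuk_rule && fuk_len,
               in_gfpp_set = gfpp_rule && gfpp_len,
               in_fkp_set = fkp_rule && fkp_len,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(ids, one_row))
  if (is.null(out))
    out <- data.frame(query_id = character(0), length = numeric(0),
                      top_models = character(0), fuk_rule = logical(0),
                      gfpp_rule = logical(0), fkp_rule = logical(0),
                      fuk_length_pass = logical(0),
                      gfpp_length_pass = logical(0),
                      fkp_length_pass = logical(0),
                      in_fuk_set = logical(0), in_gfpp_set = logical(0),
                      in_fkp_set = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("domain_calls", class(out))
  out
}

#' Predicted family from architecture calls
#'
#' Collapses the (pre-length-filter) rule memberships into a single
#' predicted family per query: FKP when the three-model rule fires,
#' otherwise FUK or GFPP by their rules, otherwise `NA`.
#'
#' @param calls a `domain_calls` data.frame.
#' @return named character vector of predicted families.
#' @export
predict_family <- function(calls) {
  stopifnot(inherits(calls, "domain_calls"))
  fam <- ifelse(calls$fkp_rule, "FKP",
                ifelse(calls$fuk_rule, "FUK",
                       ifelse(calls$gfpp_rule, "GFPP", NA_character_)))
  stats::setNames(fam, calls$query_id)
}

#' Summarize architecture calls
#'
#' @param calls a `domain_calls` data.frame.
#' @return a list with `combinations` (counts of every
#'   in_fuk/in_gfpp/in_fkp membership combination, including the
#'   all-FALSE one) and `totals` (per-set totals and `n`).
#' @export
summarize_calls <- function(calls) {
  stopifnot(inherits(calls, "domain_calls"))
  grid <- expand.grid(in_fuk_set = c(FALSE, TRUE),
                      in_gfpp_set = c(FALSE, TRUE),
                      in_fkp_set = c(FALSE, TRUE))
  grid$n <- mapply(function(f, g, k) {
    sum(calls$in_fuk_set == f & calls$in_gfpp_set == g &
          calls$in_fkp_set == k)
  }, grid$in_fuk_set, grid$in_gfpp_set, grid$in_fkp_set)
  list(combinations = grid,
       totals = c(fuk_set = sum(calls$in_fuk_set),
                  gfpp_set = sum(calls$in_gfpp_set),
                  fkp_set = sum(calls$in_fkp_set),
                  n = nrow(calls)))
}
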