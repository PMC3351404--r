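# Haplotype and nucleotide diversity (per dataset and per locality).

#' Haplotype diversity (unbiased estimator)
#'
#' \eqn{H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} with
#' \eqn{p_i = c_i/n}, the sample-size-corrected probability that two
#' randomly drawn specimens carry different haplotypes.
#'
#' @param counts vector of positive haplotype counts.
#' @return H in [0, 1]; \code{NA} (not calculable) when the sample holds
#'   fewer than two specimens.
#' @examples
#' haplotype_diversity(c(8, 1))    # 0.2222
#' haplotype_diversity(c(3, 2, 2)) # 0.7619
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(is.na(counts)) || any(counts <= 0) ||
      any(counts != round(counts)))
    stop("counts must be positive integers", call. = FALSE)
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity under pairwise deletion
#'
#' Mean over all sequence pairs of the per-site proportion of differences
#' \eqn{d_{ij}/v_{ij}}, where each pair is compared only at its own
#' pairwise-complete sites. Incomparable pairs (no shared unambiguous site)
#' are dropped from the mean; if every pair is incomparable the value is
#' not calculable.
#'
#' @param aln an \code{\link{alignment}} with at least two records.
#' @return pi (per site); \code{NA} when n < 2 or no pair is comparable.
#' @export
nucleotide_diversity <- function(aln) {
  if (aln$n < 2) return(NA_real_)
  pd <- pairwise_differences(aln)
  ut <- upper.tri(pd$diff)
  prop <- pd$diff[ut] / pd$valid[ut]
  prop <- prop[pd$valid[ut] > 0 & !is.na(pd$diff[ut])]
  if (!length(prop)) return(NA_real_)
  mean(prop)
}

#' Per-locality diversity summary
#'
#' One row per locality with at least one specimen: sample size, number of
#' haplotypes, haplotype diversity and nucleotide diversity. Localities
#' with a single specimen carry not-calculable (\code{NA}) markers.
#'
#' @param index a \code{\link{collapse_haplotypes}} result.
#' @param table optional \code{\link{read_locality_table}} result; when
#'   given, every occurrence code must be a known locality.
#' @return data.frame with columns \code{code}, \code{n}, \code{k},
#'   \code{H}, \code{pi}.
#' @export
per_locality_summary <- function(index, table = NULL) {
  codes <- sort(unique(unlist(lapply(index$occurrences, names))))
  if (!is.null(table)) {
    unknown <- setdiff(codes, table$localities$code)
    if (length(unknown))
      stop("mapping error: occurrence at unknown locality code(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(codes, function(cd) {
    counts <- vapply(index$occurrences,
                     function(o) if (cd %in% names(o)) o[[cd]] else 0L, 0L)
    counts <- counts[counts > 0L]
    n <- sum(counts)
    sub <- expand_index(index, codes = cd)
    data.frame(code = cd, n = n, k = length(counts),
               H = haplotype_diversity(counts),
               pi = if (n >= 2) nucleotide_diversity(sub) else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(code = character(0), n = integer(0), k = integer(0),
                      H = numeric(0), pi = numeric(0)))
  do.call(rbind, rows)
}

#' Dataset-level tallies across species
#'
#' Totals per species, locality counts, the range and mean of per-locality
#' sample sizes, and the sympatry fraction: the share of sampled localities
#' at which every species in the table occurs, rounded to a whole percent.
#'
#' @param table a \code{\link{read_locality_table}} result (one or more
#'   species).
#' @return list with \code{per_species} (data.frame \code{species},
#'   \code{total_n}, \code{n_localities}), \code{n_localities_any},
#'   \code{min_n}, \code{max_n}, \code{mean_n}, and
#'   \code{sympatry_percent}.
#' @export
dataset_summary <- function(table) {
  sps <- names(table$species)
  if (!length(sps)) stop("no species in table", call. = FALSE)
  per <- do.call(rbind, lapply(sps, function(sp) {
    st <- table$species[[sp]]
    data.frame(species = sp, total_n = sum(st$n), n_localities = nrow(st),
               stringsAsFactors = FALSE)
  }))
  all_n <- unlist(lapply(table$species, function(st) st$n), use.names = FALSE)
  codes_by_sp <- lapply(table$species, function(st) st$code)
  any_codes <- unique(unlist(codes_by_sp))
  all_codes <- Reduce(intersect, codes_by_sp)
  symp <- if (length(sps) < 2L || !length(any_codes)) 0 else
    round(100 * length(all_codes) / length(any_codes))
  list(per_species = per,
       n_localities_any = length(any_codes),
       min_n = min(all_n), max_n = max(all_n), mean_n = mean(all_n),
       sympatry_percent = symp)
}

# "0.2222" / "n/a" formatting used by the report tables
format_stat <- function(x, digits = 4, na = "n/a") {
  ifelse(is.na(x), na, formatC(round(x, digits), format = "f",
                               digits = digits))
}
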