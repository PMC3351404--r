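# Locality metadata and haplotype collapsing.

#' Read a locality table
#'
#' Parses a tab-separated locality table in the wide two-species dialect:
#' columns \code{code}, \code{name}, \code{lat}, \code{lon}, then per
#' species a specimen count column \code{N_<species>} and a haplotype list
#' column \code{haplotypes_<species>} (labels separated by commas or
#' semicolons). Blank count cells mean the species was not sampled at that
#' locality (absent, not zero). Additional columns (e.g. published
#' diversity values) are carried along unparsed in \code{$extra}.
#'
#' @param path path to a UTF-8 TSV file with a header row.
#' @return An object of class \code{"locality_table"}: a list with
#'   \code{localities} (data.frame \code{code}, \code{name}, \code{lat},
#'   \code{lon}) and \code{species}, a named list with one data.frame per
#'   species (\code{code}, \code{n}, list-column \code{haplotypes}),
#'   restricted to localities where the species is present.
#' @export
read_locality_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8",
                          strip.white = TRUE, quote = "")
  req <- c("code", "name", "lat", "lon")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("locality table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$code))
    stop("duplicate error: locality code(s) repeated: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "),
         call. = FALSE)
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  if (anyNA(lat) || anyNA(lon))
    stop("parse error: malformed coordinate at row(s) ",
         paste(which(is.na(lat) | is.na(lon)), collapse = ", "),
         call. = FALSE)
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("parse error: coordinate out of range", call. = FALSE)

  nspcols <- grep("^N_", names(df), value = TRUE)
  if (!length(nspcols))
    stop("locality table has no N_<species> column", call. = FALSE)
  species <- sub("^N_", "", nspcols)
  sp_tabs <- list()
  for (sp in species) {
    hcol <- paste0("haplotypes_", sp)
    if (!hcol %in% names(df))
      stop("locality table lacks column ", hcol, call. = FALSE)
    nraw <- trimws(df[[paste0("N_", sp)]])
    n <- suppressWarnings(as.integer(nraw))
    if (any(nraw != "" & is.na(n)))
      stop("parse error: malformed specimen count for species ", sp,
           call. = FALSE)
    haps <- lapply(trimws(df[[hcol]]), function(h) {
      if (h == "") character(0) else trimws(strsplit(h, "[;,]")[[1L]])
    })
    present <- nraw != "" & !is.na(n) & n > 0L
    empty_hap <- lengths(haps) == 0L
    if (any(present & empty_hap) || any(!present & !empty_hap))
      stop("inconsistent row(s) for species ", sp,
           ": haplotype list must be non-empty exactly when N > 0",
           call. = FALSE)
    sp_tabs[[sp]] <- data.frame(code = df$code[present],
                                n = n[present],
                                stringsAsFactors = FALSE)
    sp_tabs[[sp]]$haplotypes <- haps[present]
  }
  extra <- df[, setdiff(names(df), c(req, nspcols,
                                     paste0("haplotypes_", species))),
              drop = FALSE]
  structure(list(
    localities = data.frame(code = df$code, name = df$name,
                            lat = lat, lon = lon, stringsAsFactors = FALSE),
    species = sp_tabs,
    extra = extra
  ), class = "locality_table")
}

#' @export
print.locality_table <- function(x, ...) {
  cat("Locality table:", nrow(x$localities), "localities;",
      length(x$species), "species (",
      paste(names(x$species), collapse = ", "), ")\n")
  for (sp in names(x$species))
    cat("  ", sp, ": ", sum(x$species[[sp]]$n), " specimens at ",
        nrow(x$species[[sp]]), " localities\n", sep = "")
  invisible(x)
}

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences (exact match after normalization) share one
#' haplotype. Sequences containing ambiguity codes are never merged into
#' compatible haplotypes; identity is literal string equality, which keeps
#' the collapse conservative and deterministic. Labels are assigned
#' \code{H1, H2, ...} in order of first appearance unless \code{labels}
#' supplies replacements (in first-appearance order).
#'
#' @param aln an \code{\link{alignment}}.
#' @param locality_of named character vector mapping every sequence id to a
#'   locality code.
#' @param labels optional character vector of haplotype labels, one per
#'   distinct haplotype in first-appearance order.
#' @return Object of class \code{"haplotype_index"}: list with
#'   \code{haplotypes} (data.frame \code{label}, \code{sequence},
#'   \code{count}), \code{occurrences} (named list: label -> named integer
#'   vector of per-locality counts), \code{L} and \code{n_seq}.
#' @export
collapse_haplotypes <- function(aln, locality_of, labels = NULL) {
  missing_ids <- setdiff(aln$ids, names(locality_of))
  if (length(missing_ids))
    stop("mapping error: no locality assignment for id(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  loc <- as.character(locality_of[aln$ids])
  f <- factor(aln$seqs, levels = unique(aln$seqs))
  k <- nlevels(f)
  labs <- if (is.null(labels)) paste0("H", seq_len(k)) else {
    if (length(labels) != k)
      stop("labels must have length ", k, call. = FALSE)
    as.character(labels)
  }
  counts <- as.integer(table(f))
  occ <- lapply(seq_len(k), function(i) {
    tab <- table(loc[as.integer(f) == i])
    stats::setNames(as.integer(tab), names(tab))
  })
  names(occ) <- labs
  structure(list(
    haplotypes = data.frame(label = labs, sequence = levels(f),
                            count = counts, stringsAsFactors = FALSE),
    occurrences = occ, L = aln$L, n_seq = aln$n
  ), class = "haplotype_index")
}

#' @export
print.haplotype_index <- function(x, ...) {
  cat("Haplotype index:", nrow(x$haplotypes), "haplotypes from", x$n_seq,
      "sequences (", x$L, "sites )\n")
  invisible(x)
}

# alignment of one copy of each haplotype (ids = labels)
haplotype_alignment <- function(index) {
  alignment(index$haplotypes$label, index$haplotypes$sequence)
}

# expand an index back to one record per specimen, optionally restricted to
# a set of haplotype labels or locality codes
expand_index <- function(index, labels = NULL, codes = NULL) {
  hp <- index$haplotypes
  if (!is.null(labels)) hp <- hp[hp$label %in% labels, , drop = FALSE]
  ids <- character(0); seqs <- character(0)
  for (i in seq_len(nrow(hp))) {
    occ <- index$occurrences[[hp$label[i]]]
    if (!is.null(codes)) occ <- occ[names(occ) %in% codes]
    tot <- sum(occ)
    if (tot == 0L) next
    ids <- c(ids, paste0(hp$label[i], "_", seq_len(tot)))
    seqs <- c(seqs, rep(hp$sequence[i], tot))
  }
  if (!length(ids)) return(NULL)
  alignment(ids, seqs)
}
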