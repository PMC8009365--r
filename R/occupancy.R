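#' Construct a biome occupancy matrix
#'
#' A binary taxa-by-biomes presence matrix, the central object distinguishing
#' the multiple-biome and single-biome (modal) coding approaches. Every taxon
#' must occupy at least one biome; under \code{mode = "single"} every taxon
#' occupies exactly one.
#'
#' @param presence binary matrix (taxa in rows, biomes in columns) with row
#'   names (taxa) and column names (biomes).
#' @param mode \code{"multiple"} (default) or \code{"single"}.
#' @return an object of class \code{"occupancy_matrix"} (a 0/1 integer matrix
#'   with a \code{mode} attribute).
#' @export
occupancy_matrix <- function(presence, mode = c("multiple", "single")) {
  mode <- match.arg(mode)
  m <- as.matrix(presence)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("presence matrix must have taxon row names and biome column names")
  if (anyDuplicated(rownames(m))) stop("duplicate taxon names")
  if (anyDuplicated(colnames(m))) stop("duplicate biome names")
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    bad <- which(is.na(m) | !(m %in% c(0L, 1L)), arr.ind = TRUE)[1L, ]
    stop("non-binary cell at taxon \"", rownames(m)[bad[1L]], "\", biome \"",
         colnames(m)[bad[2L]], "\"")
  }
  rs <- rowSums(m)
  if (any(rs == 0L))
    stop("all-zero row (taxon occupies no biome): ",
         paste(rownames(m)[rs == 0L], collapse = ", "))
  if (mode == "single" && any(rs != 1L))
    stop("mode=\"single\" requires exactly one biome per taxon; offending: ",
         paste(rownames(m)[rs != 1L], collapse = ", "))
  structure(m, mode = mode, class = c("occupancy_matrix", "matrix", "array"))
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("Occupancy matrix (", nrow(x), " taxa x ", ncol(x), " biomes, mode=",
      attr(x, "mode"), ")\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Read a biome occupancy matrix
#'
#' Two dialects are supported: \code{"csv"} — a header row naming the biomes
#' followed by one row per taxon of 0/1 cells; and \code{"geography"} — the
#' LAGRANGE/PHYLIP-style file used by biogeography tools, with an
#' \code{"ntaxa nbiomes"} header line then one \code{"taxon 0/1-string"} line
#' per taxon (biome names taken from \code{biomes}, or B1..Bk).
#'
#' @param path input file.
#' @param dialect \code{"csv"} or \code{"geography"}.
#' @param biomes optional biome names for the geography dialect.
#' @param mode passed to \code{\link{occupancy_matrix}}.
#' @return an \code{"occupancy_matrix"}.
#' @export
read_occupancy <- function(path, dialect = c("csv", "geography"), biomes = NULL,
                           mode = c("multiple", "single")) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("occupancy CSV needs a taxon column plus biome columns")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    return(occupancy_matrix(m, mode = mode))
  }
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  hdr <- scan(text = ln[1L], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L) stop("geography header must be \"ntaxa nbiomes\"")
  n_tax <- hdr[1L]; n_bio <- hdr[2L]
  if (length(ln) - 1L != n_tax)
    stop("geography file declares ", n_tax, " taxa but has ", length(ln) - 1L, " rows")
  rows <- strsplit(trimws(ln[-1L]), "\\s+")
  taxa <- vapply(rows, `[[`, "", 1L)
  pat <- vapply(rows, function(r) paste(r[-1L], collapse = ""), "")
  if (any(nchar(pat) != n_bio))
    stop("0/1 string length mismatch with declared biome count for taxon ",
         taxa[which(nchar(pat) != n_bio)[1L]])
  if (any(grepl("[^01]", pat)))
    stop("non-binary character in geography row for taxon ",
         taxa[which(grepl("[^01]", pat))[1L]])
  m <- do.call(rbind, lapply(pat, function(p) as.integer(strsplit(p, "")[[1L]])))
  rownames(m) <- taxa
  colnames(m) <- if (!is.null(biomes)) biomes else paste0("B", seq_len(n_bio))
  occupancy_matrix(m, mode = mode)
}

#' Write a biome occupancy matrix
#'
#' @param occ an \code{"occupancy_matrix"}.
#' @param path output file.
#' @param dialect \code{"csv"} or \code{"geography"}.
#' @return \code{path}, invisibly.
#' @export
write_occupancy <- function(occ, path, dialect = c("csv", "geography")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- data.frame(taxon = rownames(occ), unclass(occ), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    ln <- c(paste(nrow(occ), ncol(occ)),
            paste(rownames(occ), apply(unclass(occ), 1L, paste, collapse = "")))
    writeLines(ln, path)
  }
  invisible(path)
}

#' Collapse a multiple-biome matrix to modal (single) biome coding
#'
#' Implements the single-biome-per-species coding: each taxon is reduced to
#' its modal biome, the biome forming the largest proportion of its range.
#' Range proportions are an explicit input (\code{weights}); ties are broken
#' deterministically towards the lowest biome index in the fixed biome order.
#' Specialists are unchanged, and the operation is idempotent.
#'
#' @param occ an \code{"occupancy_matrix"}.
#' @param weights numeric matrix of per-taxon biome range proportions, same
#'   dimensions and dimnames as \code{occ}; each row must be non-negative,
#'   positive only on occupied biomes, and sum to 1. May be omitted when every
#'   taxon is already a specialist.
#' @return an \code{"occupancy_matrix"} with \code{mode = "single"}.
#' @seealso \code{\link{make_modal_weights}} for generating synthetic weights.
#' @export
collapse_to_modal <- function(occ, weights = NULL) {
  m <- unclass(occ)
  if (is.null(weights)) {
    if (any(rowSums(m) > 1L))
      stop("weights required when any taxon occupies more than one biome")
    weights <- m * 1.0
  }
  w <- as.matrix(weights)
  if (!identical(dim(w), dim(m))) stop("weights dimensions must match occupancy")
  if (!is.null(rownames(w)) && !identical(rownames(w), rownames(m)))
    w <- w[rownames(m), colnames(m), drop = FALSE]
  if (any(w < 0)) stop("negative weight")
  if (any(w[m == 0L] > 0)) {
    bad <- which(w > 0 & m == 0L, arr.ind = TRUE)[1L, ]
    stop("weight on unoccupied biome: taxon \"", rownames(m)[bad[1L]],
         "\", biome \"", colnames(m)[bad[2L]], "\"")
  }
  if (any(abs(rowSums(w) - 1) > 1e-8)) stop("weights must sum to 1 per taxon")
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  modal <- apply(w, 1L, which.max)  # which.max: first (lowest index) wins ties
  out[cbind(seq_len(nrow(m)), modal)] <- 1L
  occupancy_matrix(out, mode = "single")
}

# taxa-to-tree alignment; returns occ with rows in tip order
align_occupancy <- function(occ, tree) {
  if (!setequal(rownames(occ), tree$tip.label))
    stop("occupancy taxa and tree tips differ: missing [",
         paste(setdiff(tree$tip.label, rownames(occ)), collapse = ", "),
         "], extra [", paste(setdiff(rownames(occ), tree$tip.label), collapse = ", "), "]")
  m <- unclass(occ)[tree$tip.label, , drop = FALSE]
  structure(m, mode = attr(occ, "mode"), class = class(occ))
}

# occupancy rows as integer state bitmasks (aligned to a biome order)
occ_states <- function(occ, biomes) {
  m <- unclass(occ)
  if (!setequal(colnames(m), biomes))
    stop("occupancy biomes do not match availability biomes")
  m <- m[, biomes, drop = FALSE]
  as.integer(m %*% 2L^(seq_along(biomes) - 1L))
}
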