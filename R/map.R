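# Genetic maps: the marker panel lives on the three major Drosophila
# chromosomes (X, 2, 3), with arms (X, 2L, 2R, 3L, 3R) annotated for
# reporting.  Positions are cM on a within-chromosome coordinate; the two
# arms of an autosome share one axis with the centromere at the arm
# boundary.  Chromosome 4 (no recombination, a single marker in the study)
# is deliberately unsupported.

.arm_chr <- c(X = "X", "2L" = "2", "2R" = "2", "3L" = "3", "3R" = "3")

# Arm lengths (cM) approximating the D. melanogaster standard map:
# X ~66, chromosome 2 ~108, chromosome 3 ~111.
.default_arm_lengths <- c(X = 66, "2L" = 55, "2R" = 53, "3L" = 47, "3R" = 64)

#' Build a marker panel on the major Drosophila chromosomes
#'
#' Creates a `genmap` object: one row per marker with its arm, chromosome
#' and cM position.  Defaults reproduce the study's 87-SNP panel
#' (X = 16, 2L = 22, 2R = 17, 3L = 12, 3R = 20).  Markers are evenly
#' spaced along each arm unless explicit positions are supplied; a
#' single-marker arm places the marker at the arm midpoint.
#'
#' @param counts Named integer vector of marker counts per arm; names must
#'   be a subset of `c("X","2L","2R","3L","3R")`.
#' @param arm_lengths Named numeric vector of arm lengths in cM.
#' @param positions Optional named list of explicit within-arm positions
#'   (cM from the arm start), overriding even spacing for those arms.
#' @return A data frame of class `genmap` with columns `marker`, `chr`,
#'   `arm`, `pos` (cM on the chromosome axis) and attribute `chr_len`.
#' @examples
#' map <- make_marker_panel()
#' nrow(map)  # 87
#' @export
make_marker_panel <- function(counts = c(X = 16, "2L" = 22, "2R" = 17,
                                         "3L" = 12, "3R" = 20),
                              arm_lengths = .default_arm_lengths,
                              positions = NULL) {
  if (any(!names(counts) %in% names(.arm_chr))) {
    bad <- setdiff(names(counts), names(.arm_chr))
    stop("unsupported chromosome arm(s): ", paste(bad, collapse = ", "),
         " (only X, 2L, 2R, 3L, 3R are supported; chromosome 4 is out of scope)")
  }
  stopifnot(all(counts >= 1), all(arm_lengths[names(counts)] > 0))
  rows <- lapply(names(counts), function(arm) {
    L <- unname(arm_lengths[[arm]])
    k <- as.integer(counts[[arm]])
    p <- if (!is.null(positions) && !is.null(positions[[arm]])) {
      sort(as.numeric(positions[[arm]]))
    } else if (k == 1L) L / 2 else seq(0, L, length.out = k)
    if (any(p < 0) || any(p > L)) stop("positions outside arm ", arm)
    # offset: right arms start after the left arm of the same chromosome
    off <- switch(arm, "2R" = arm_lengths[["2L"]], "3R" = arm_lengths[["3L"]], 0)
    data.frame(marker = sprintf("%s_%02d", arm, seq_len(length(p))),
               chr = .arm_chr[[arm]], arm = arm, pos = p + off,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map <- map[order(match(map$chr, c("X", "2", "3")), map$pos), ]
  rownames(map) <- NULL
  used_arms <- names(counts)
  chr_len <- vapply(unique(map$chr), function(cc) {
    arms <- intersect(names(.arm_chr)[.arm_chr == cc], used_arms)
    sum(arm_lengths[arms])
  }, 0)
  structure(map, chr_len = chr_len, class = c("genmap", "data.frame"))
}

# construct a genmap from bare columns (used when re-estimating maps)
as_genmap <- function(marker, chr, arm, pos, chr_len = NULL) {
  map <- data.frame(marker = marker, chr = chr, arm = arm, pos = pos,
                    stringsAsFactors = FALSE)
  if (is.null(chr_len)) {
    chr_len <- tapply(map$pos, map$chr, max)
    chr_len <- stats::setNames(as.numeric(chr_len), names(chr_len))
  }
  validate_genmap(structure(map, chr_len = chr_len,
                            class = c("genmap", "data.frame")))
}

validate_genmap <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker", "chr", "arm", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) stop("duplicated marker names")
  if (any(map$chr == "4")) stop("chromosome 4 is out of scope")
  for (cc in unique(map$chr)) {
    p <- map$pos[map$chr == cc]
    if (is.unsorted(p)) stop("marker positions not nondecreasing on chromosome ", cc)
  }
  map
}

#' @export
print.genmap <- function(x, ...) {
  cat("Genetic map:", nrow(x), "markers on",
      length(unique(x$chr)), "chromosome(s)\n")
  tab <- table(x$arm)
  cat("  per arm:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  len <- attr(x, "chr_len")
  cat("  chromosome lengths (cM):",
      paste(names(len), round(len, 1), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Total map length
#'
#' Sum of per-chromosome marker spans, optionally restricted to autosomes.
#'
#' @param map A `genmap`.
#' @param chr Chromosomes to include; default all.
#' @return Length in cM.
#' @export
map_length <- function(map, chr = unique(map$chr)) {
  sum(vapply(chr, function(cc) {
    p <- map$pos[map$chr == cc]
    if (length(p) < 2) 0 else max(p) - min(p)
  }, 0))
}

#' Convert a position between two maps of the same markers
#'
#' Piecewise-linear interpolation anchored at shared marker positions;
#' used to express, e.g., an expanded-AIL-scale position on the reference
#' F2 scale (or the reverse) the way dual-scale QTL tables report
#' intervals.
#'
#' @param chr Chromosome of the position.
#' @param pos Position (cM) on the `from` map scale.
#' @param from,to `genmap` objects sharing marker names.
#' @return Position in cM on the `to` scale.
#' @export
convert_map_position <- function(chr, pos, from, to) {
  f <- from[from$chr == chr, ]
  t2 <- to[to$chr == chr, ]
  m <- intersect(f$marker, t2$marker)
  if (length(m) < 2) stop("need at least two shared markers on chromosome ", chr)
  stats::approx(f$pos[match(m, f$marker)], t2$pos[match(m, t2$marker)],
                xout = pos, rule = 2, ties = list("ordered", mean))$y
}
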