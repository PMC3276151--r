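# Plain-text file formats.  The cross file is a single CSV in the
# familiar rotated-header layout: row 1 holds id, sex, the phenotype
# names and the marker names; rows 2 and 3 hold the chromosome and cM of
# each marker (blank under the id/sex/phenotype columns); every further
# row is one individual.  Genotypes use A / H / B, hemizygous male X uses
# A / B, and missing is "-".  Outline files are long-format tables, one
# row per vertex.

.code_to_file <- c(AA = "A", AB = "H", BB = "B", A = "A", B = "B")

#' Write a cross population to a CSV file
#'
#' @param pop A `cross_pop`.
#' @param path Output file.
#' @return `path`, invisibly.  `read_cross(write_cross(pop))` reproduces
#'   the genotypes, phenotypes and map exactly.
#' @export
write_cross <- function(pop, path) {
  map <- pop$map
  ph <- setdiff(names(pop$pheno), "id")
  ph <- ph[vapply(pop$pheno[ph], is.numeric, TRUE)]  # format carries numeric traits
  g <- pop$geno[, map$marker, drop = FALSE]
  gf <- matrix(.code_to_file[g], nrow(g), ncol(g))
  gf[is.na(g)] <- "-"
  hdr1 <- c("id", "sex", ph, map$marker)
  hdr2 <- c("", "", rep("", length(ph)), map$chr)
  hdr3 <- c("", "", rep("", length(ph)), format(map$pos, digits = 12))
  body <- cbind(pop$pheno$id, pop$sex,
                if (length(ph)) sapply(pop$pheno[ph], function(v) format(v, digits = 12)) else NULL,
                gf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr1, collapse = ","), con)
  writeLines(paste(hdr2, collapse = ","), con)
  writeLines(paste(hdr3, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a cross population from a CSV file
#'
#' @param path A file written by [write_cross()] (or hand-assembled in
#'   the same layout).
#' @param generation Generation label to attach (`NA` to leave unset).
#' @return A `cross_pop` (without haplotypes).  The genotyped flag is
#'   derived from the data: individuals whose genotypes are all missing
#'   are flagged ungenotyped, as for non-tail individuals under selective
#'   genotyping.
#' @export
read_cross <- function(path, generation = NA_integer_) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("cross file has no individuals: ", path)
  split1 <- strsplit(lines, ",", fixed = TRUE)
  hdr <- split1[[1]]
  chrs <- split1[[2]]
  poss <- split1[[3]]
  if (length(chrs) != length(hdr) || length(poss) != length(hdr)) {
    stop("malformed header block (lines 1-3 differ in length)")
  }
  is_marker <- chrs != ""
  if (!any(is_marker)) stop("no marker columns found")
  if (hdr[1] != "id" || hdr[2] != "sex") {
    stop("first two columns must be 'id' and 'sex'")
  }
  ph_cols <- which(!is_marker)[-(1:2)]
  mk_cols <- which(is_marker)
  if (any(mk_cols < max(c(2, ph_cols)))) {
    stop("marker columns must follow the phenotype columns")
  }
  marker <- hdr[mk_cols]
  chr <- chrs[mk_cols]
  pos <- as.numeric(poss[mk_cols])
  if (anyNA(pos)) stop("non-numeric marker position in header line 3")
  arm <- chr  # arm annotation is not stored in the file format
  n <- length(lines) - 3
  ids <- character(n)
  sexes <- character(n)
  pheno <- matrix(NA_real_, n, length(ph_cols))
  geno <- matrix(NA_character_, n, length(mk_cols))
  valid <- c(A = "A", H = "H", B = "B", `-` = "-")
  for (i in seq_len(n)) {
    f <- split1[[i + 3]]
    if (length(f) != length(hdr)) {
      stop("line ", i + 3, ": expected ", length(hdr), " fields, found ",
           length(f))
    }
    ids[i] <- f[1]
    sexes[i] <- f[2]
    if (length(ph_cols)) {
      pv <- suppressWarnings(as.numeric(f[ph_cols]))
      bad_ph <- which(is.na(pv) & !trimws(f[ph_cols]) %in% c("", "NA", "-"))
      if (length(bad_ph)) {
        stop("line ", i + 3, ": non-numeric phenotype value '",
             f[ph_cols][bad_ph[1]], "' in column ", hdr[ph_cols][bad_ph[1]])
      }
      pheno[i, ] <- pv
    }
    gi <- f[mk_cols]
    bad <- which(!gi %in% valid)
    if (length(bad)) {
      stop("line ", i + 3, ": unknown genotype code '", gi[bad[1]],
           "' at marker ", marker[bad[1]])
    }
    geno[i, ] <- gi
  }
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    stop("duplicated individual id '", d, "' at line ",
         3 + which(ids == d)[2])
  }
  # decode: autosomes A/H/B -> AA/AB/BB; male X A/B stays hemizygous
  out <- matrix(NA_character_, n, length(mk_cols),
                dimnames = list(ids, marker))
  for (j in seq_along(mk_cols)) {
    gj <- geno[, j]
    if (chr[j] == "X") {
      if (any(gj == "H" & sexes == "M")) {
        stop("heterozygous X genotype for male individual at marker ",
             marker[j])
      }
      dec <- c(A = "A", H = "AB", B = "B", `-` = NA)
    } else {
      dec <- c(A = "AA", H = "AB", B = "BB", `-` = NA)
    }
    out[, j] <- dec[gj]
  }
  map <- as_genmap(marker, chr, arm, pos)
  phd <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (k in seq_along(ph_cols)) phd[[hdr[ph_cols[k]]]] <- pheno[, k]
  structure(list(geno = out, map = map, sex = sexes, pheno = phd,
                 genotyped = unname(rowSums(!is.na(out)) > 0),
                 generation = generation, haplotypes = NULL),
            class = "cross_pop")
}

#' Write outlines to a long-format table
#'
#' @param outlines Named list of two-column coordinate matrices.
#' @param path Output file.
#' @param side Optional per-outline side labels (`"left"`/`"right"`).
#' @return `path`, invisibly.
#' @export
write_outlines <- function(outlines, path, side = NULL) {
  rows <- lapply(seq_along(outlines), function(i) {
    xy <- outlines[[i]]
    data.frame(outline_id = names(outlines)[i] %||% as.character(i),
               point_index = seq_len(nrow(xy)),
               x = xy[, 1], y = xy[, 2],
               side = if (is.null(side)) NA_character_ else side[i],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read outlines from a long-format table
#'
#' Expects a header row with at least `outline_id`, `point_index`, `x`,
#' `y`; rows are re-ordered by `point_index` within each outline.
#'
#' @param path Input file.
#' @return Named list of coordinate matrices (with a `side` attribute
#'   when the column is present).
#' @export
read_outlines <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("outline_id", "point_index", "x", "y")
  if (!all(need %in% names(d))) {
    stop("outline file must have columns ", paste(need, collapse = ", "))
  }
  out <- lapply(split(d, d$outline_id), function(o) {
    o <- o[order(o$point_index), ]
    m <- cbind(x = o$x, y = o$y)
    if ("side" %in% names(o)) attr(m, "side") <- o$side[1]
    m
  })
  out[unique(d$outline_id)]
}

#' Read a candidate-locus position table
#'
#' @param path CSV with columns `name`, `chr`, `pos` (cM).
#' @return Data frame suitable for [candidate_resampling_test()].
#' @export
read_candidates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "chr", "pos") %in% names(d))) {
    stop("candidate file must have columns name, chr, pos")
  }
  d$chr <- as.character(d$chr)
  d
}
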