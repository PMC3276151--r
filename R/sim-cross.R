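# Cross simulation at the haplotype level.  Each chromosome of an
# individual is one or two haplotypes; a haplotype is a run-length list of
# founder-allele segments (allele 1 = parent A, b3852-like; allele 2 =
# parent B, Sam-like).  Female meiosis drops crossovers under the Haldane
# model (Poisson count, mean = map length / 100, positions uniform in cM);
# male meiosis transmits intact chromosomes, as in Drosophila.  Sons
# receive their X from their mother only.

new_hap <- function(L, allele) list(ends = L, al = as.integer(allele))

# founder allele at position(s) pos (vectorized)
hap_allele <- function(hap, pos) {
  hap$al[findInterval(pos, hap$ends, left.open = TRUE) + 1L]
}

# recombine two haplotypes at sorted crossover positions xo, starting on
# haplotype `start`
recombine_haps <- function(h1, h2, L, xo, start) {
  haps <- list(h1, h2)
  bnds <- c(xo, L)
  cur <- start
  prev <- 0
  ends <- numeric(0)
  al <- integer(0)
  for (b in bnds) {
    if (b > prev) {
      h <- haps[[cur]]
      i1 <- findInterval(prev, h$ends, left.open = TRUE) + 1L
      i2 <- findInterval(b, h$ends, left.open = TRUE) + 1L
      ends <- c(ends, pmin(h$ends[i1:i2], b))
      al <- c(al, h$al[i1:i2])
    }
    prev <- b
    cur <- 3L - cur
  }
  keep <- ends > c(0, ends[-length(ends)])
  ends <- ends[keep]
  al <- al[keep]
  rl <- rle(al)
  list(ends = ends[cumsum(rl$lengths)], al = rl$values)
}

# one meiotic product from a haplotype pair
meiosis <- function(haps, L, recombine = TRUE) {
  if (length(haps) == 1L) return(haps[[1L]])
  if (!recombine) return(haps[[sample.int(2L, 1L)]])
  nxo <- stats::rpois(1L, L / 100)
  start <- sample.int(2L, 1L)
  if (nxo == 0L) return(haps[[start]])
  recombine_haps(haps[[1L]], haps[[2L]], L, sort(stats::runif(nxo, 0, L)), start)
}

# genotype code at position(s) on one chromosome of one individual:
# "AA"/"AB"/"BB", or hemizygous "A"/"B" when only one haplotype is carried
geno_code_at <- function(chrs, chr, pos) {
  haps <- chrs[[chr]]
  a1 <- hap_allele(haps[[1L]], pos)
  if (length(haps) == 1L) return(c("A", "B")[a1])
  a2 <- hap_allele(haps[[2L]], pos)
  c("AA", "AB", "BB")[a1 + a2 - 1L]
}

#' Describe a cross design
#'
#' Captures the breeding scheme: final generation `t` (`t = 2` is an F2,
#' `t = 17` the study's advanced intercross), the number of phenotyped
#' males sampled from the final generation, the census size of the
#' intermediate random-mating generations, optional viability selection,
#' and the per-side tail count used for selective genotyping.
#'
#' @param t Final generation (integer >= 2).
#' @param n_males Number of phenotyped males sampled at generation `t`.
#' @param census Census size of generations F2..F(t-1); constant, equal
#'   sex ratio.
#' @param tails Per-side tail count for selective genotyping (used by
#'   [select_tails()]); the study genotyped 47 + 47 of 344 F17 males.
#' @param selection Optional list of viability-selection terms, each
#'   `list(chr =, pos =, genotype =, fitness =)` with relative fitness in
#'   (0, 1], applied by rejection sampling at zygote formation.
#' @param reciprocal_mix If `TRUE` (default) the F1 males are a pooled mix
#'   of reciprocal crosses, so their single X is parent-A or parent-B with
#'   equal probability; no parent-of-origin effects are modeled.
#' @param female_only_recombination If `TRUE` (default, the Drosophila
#'   case) crossovers occur only in female meiosis; set `FALSE` for a
#'   generic intercross in which both sexes recombine.
#' @return A list of class `cross_design`.
#' @export
cross_design <- function(t = 2L, n_males = if (t == 2L) 367L else 344L,
                         census = 500L, tails = 47L, selection = NULL,
                         reciprocal_mix = TRUE,
                         female_only_recombination = TRUE) {
  t <- as.integer(t)
  if (t < 2L) stop("final generation t must be >= 2 (t = 2 is an F2)")
  if (census < 2L) stop("census must be >= 2")
  if (!is.null(selection)) {
    for (s in selection) {
      stopifnot(all(c("chr", "pos", "genotype", "fitness") %in% names(s)))
      if (s$fitness <= 0 || s$fitness > 1) stop("fitnesses must lie in (0, 1]")
    }
  }
  structure(list(t = t, n_males = as.integer(n_males),
                 census = as.integer(census), tails = as.integer(tails),
                 selection = selection, reciprocal_mix = reciprocal_mix,
                 female_only_recombination = female_only_recombination),
            class = "cross_design")
}

# relative fitness of an offspring's chromosome set under the design's
# viability selection
.viability <- function(chrs, selection) {
  w <- 1
  for (s in selection) {
    if (identical(geno_code_at(chrs, as.character(s$chr), s$pos), s$genotype))
      w <- w * s$fitness
  }
  w
}

# one offspring of given sex; rejection-samples against viability selection
.make_offspring <- function(mother, father, sex, chr_lens, design,
                            max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    chrs <- lapply(names(chr_lens), function(cc) {
      L <- chr_lens[[cc]]
      egg <- meiosis(mother$chrs[[cc]], L, recombine = TRUE)
      if (cc == "X") {
        if (sex == "M") return(list(egg))
        return(list(egg, father$chrs[["X"]][[1L]]))
      }
      sperm <- meiosis(father$chrs[[cc]], L,
                       recombine = !design$female_only_recombination)
      list(egg, sperm)
    })
    names(chrs) <- names(chr_lens)
    if (is.null(design$selection)) return(list(sex = sex, chrs = chrs))
    w <- .viability(chrs, design$selection)
    if (w >= 1 || stats::runif(1) < w) return(list(sex = sex, chrs = chrs))
  }
  loci <- vapply(design$selection,
                 function(s) paste0(s$chr, "@", s$pos), "")
  stop("viability selection too strong: no surviving zygote in ",
       max_tries, " attempts at locus/loci ", paste(loci, collapse = ", "))
}

.f1_pool <- function(n_f, n_m, chr_lens, reciprocal_mix) {
  het <- function(L) list(new_hap(L, 1L), new_hap(L, 2L))
  base <- lapply(chr_lens, het)
  females <- replicate(n_f, list(sex = "F", chrs = base), simplify = FALSE)
  males <- replicate(n_m, {
    chrs <- base
    xa <- if (reciprocal_mix) sample.int(2L, 1L) else 1L
    chrs[["X"]] <- list(new_hap(chr_lens[["X"]], xa))
    list(sex = "M", chrs = chrs)
  }, simplify = FALSE)
  list(F = females, M = males)
}

.next_generation <- function(pool, n_f, n_m, chr_lens, design) {
  n <- n_f + n_m
  sexes <- c(rep("F", n_f), rep("M", n_m))
  mi <- sample.int(length(pool$F), n, replace = TRUE)
  fi <- sample.int(length(pool$M), n, replace = TRUE)
  off <- vector("list", n)
  for (i in seq_len(n)) {
    off[[i]] <- .make_offspring(pool$F[[mi[i]]], pool$M[[fi[i]]],
                                sexes[i], chr_lens, design)
  }
  list(F = off[sexes == "F"], M = off[sexes == "M"])
}

#' Simulate an intercross or advanced intercross population
#'
#' Runs the breeding scheme in [cross_design()] on a marker map and
#' returns the phenotyped male sample of the final generation with its
#' marker genotypes.  Haplotypes are retained (attribute-level) so latent
#' QTL genotypes at arbitrary positions can be extracted later by
#' [assign_phenotypes()].
#'
#' @param design A [cross_design()].
#' @param map A `genmap` ([make_marker_panel()]).
#' @param seed Integer seed; identical seeds give identical populations.
#' @return An object of class `cross_pop`: genotype matrix (codes
#'   `"AA"/"AB"/"BB"` on autosomes, hemizygous `"A"/"B"` on the male X),
#'   phenotype table, genotyped flags, generation label and the map.
#' @examples
#' map <- make_marker_panel(c("2L" = 5), arm_lengths = c("2L" = 50))
#' f2 <- simulate_cross(cross_design(t = 2, n_males = 20), map, seed = 1)
#' f2
#' @export
simulate_cross <- function(design, map, seed = NULL) {
  stopifnot(inherits(design, "cross_design"))
  map <- validate_genmap(map)
  if (nrow(map) == 0) stop("empty map")
  chr_lens <- as.list(attr(map, "chr_len"))
  if (!"X" %in% names(chr_lens)) {
    # an all-autosome map still needs an X for sex bookkeeping
    chr_lens <- c(chr_lens, list(X = 1))
  }
  chr_lens <- chr_lens[order(match(names(chr_lens), c("X", "2", "3")))]
  with_seed(seed, {
    n_f <- ceiling(design$census / 2)
    n_m <- design$census - n_f
    pool <- .f1_pool(n_f, n_m, chr_lens, design$reciprocal_mix)
    if (design$t > 2L) {
      for (g in seq_len(design$t - 2L)) {
        pool <- .next_generation(pool, n_f, n_m, chr_lens, design)
      }
    }
    n <- design$n_males
    mi <- sample.int(length(pool$F), n, replace = TRUE)
    fi <- sample.int(length(pool$M), n, replace = TRUE)
    males <- vector("list", n)
    for (i in seq_len(n)) {
      males[[i]] <- .make_offspring(pool$F[[mi[i]]], pool$M[[fi[i]]],
                                    "M", chr_lens, design)
    }
    ids <- sprintf("ind_%04d", seq_len(n))
    geno <- matrix(NA_character_, n, nrow(map),
                   dimnames = list(ids, map$marker))
    for (cc in unique(map$chr)) {
      sel <- map$chr == cc
      pos <- map$pos[sel]
      for (i in seq_len(n)) {
        geno[i, sel] <- geno_code_at(males[[i]]$chrs, cc, pos)
      }
    }
    structure(list(geno = geno, map = map,
                   sex = rep("M", n),
                   pheno = data.frame(id = ids, stringsAsFactors = FALSE),
                   genotyped = rep(TRUE, n),
                   generation = design$t, design = design,
                   haplotypes = males),
              class = "cross_pop")
  })
}

#' @export
print.cross_pop <- function(x, ...) {
  cat("Simulated cross population (F", x$generation, ")\n", sep = "")
  cat("  ", nrow(x$geno), " phenotyped males, ", ncol(x$geno),
      " markers, ", sum(x$genotyped), " genotyped\n", sep = "")
  ph <- setdiff(names(x$pheno), "id")
  if (length(ph)) cat("  phenotypes:", paste(ph, collapse = ", "), "\n")
  invisible(x)
}

# numeric additive coding (-1/0/+1; hemizygous A/B -> -1/+1) and dominance
# coding (AB -> 1) from character genotype codes
geno_xz <- function(g) {
  x <- c(AA = -1, AB = 0, BB = 1, A = -1, B = 1)[g]
  z <- as.numeric(g == "AB")
  z[is.na(x)] <- NA
  list(x = unname(x), z = z)
}
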