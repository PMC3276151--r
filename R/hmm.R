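# Hidden Markov model over intercross genotype classes on a scan grid,
# and multiple imputation of complete genotypes from it.  Autosomes carry
# three classes (AA/AB/BB) driven by two independent haploid chains with
# Haldane transition probabilities; the male X carries two hemizygous
# classes (A/B) from a single chain.  Emissions allow a genotyping error
# rate epsilon: probability 1 - eps for the observed class, eps split
# over the others; missing genotypes emit uniformly.  All phenotyped
# individuals are male, matching the study design.

# F2 transition matrix between genotype classes across a gap with
# recombination fraction r (two independent meioses)
.trans_f2 <- function(r) {
  s <- 1 - r
  matrix(c(s^2, 2 * r * s, r^2,
           r * s, s^2 + r^2, r * s,
           r^2, 2 * r * s, s^2),
         3, 3, byrow = TRUE)
}

.trans_x <- function(r) matrix(c(1 - r, r, r, 1 - r), 2, 2, byrow = TRUE)

# n x S slice of an n x P x S array at position p (robust to n == 1)
.slab <- function(arr, p) matrix(arr[, p, ], dim(arr)[1], dim(arr)[3])


# emission matrix (n x S) for one grid position; `obs` is the character
# genotype column at that marker or NULL for a non-marker position
.emission <- function(obs, n, S, eps) {
  E <- matrix(1, n, S)
  if (is.null(obs)) return(E)
  codes <- if (S == 3L) c("AA", "AB", "BB") else c("A", "B")
  idx <- match(obs, codes)
  typed <- which(!is.na(idx))
  if (length(typed)) {
    E[typed, ] <- eps / (S - 1)
    E[cbind(typed, idx[typed])] <- 1 - eps
  }
  bad <- !is.na(obs) & is.na(idx)
  if (any(bad)) stop("genotype code(s) not valid here: ",
                     paste(unique(obs[bad]), collapse = ", "))
  E
}

#' Conditional genotype probabilities on a scan grid
#'
#' Runs forward-backward over each chromosome at marker positions plus a
#' regular step grid, giving per-individual posterior probabilities of
#' the intercross genotype classes given all marker data on the
#' chromosome.
#'
#' @param pop A `cross_pop` (all individuals male; ungenotyped
#'   individuals simply have all-missing observations and receive the
#'   population-prior posteriors).
#' @param map Map to scan on (default the population's map; pass an
#'   [estimate_map()] result to scan an AIL on its expanded scale).
#' @param step Grid step in cM (> 0).
#' @param error_prob Genotyping error rate epsilon in `[0, 0.5)`.
#' @return Object of class `genoprob` with per-chromosome positions,
#'   posteriors and forward variables (retained for imputation), plus a
#'   flat `grid` table.
#' @export
genotype_probabilities <- function(pop, map = pop$map, step = 1,
                                   error_prob = 1e-4) {
  if (step <= 0) stop("step must be > 0")
  if (error_prob < 0 || error_prob >= 0.5) stop("error_prob must be in [0, 0.5)")
  map <- validate_genmap(map)
  geno <- pop$geno[, map$marker, drop = FALSE]
  n <- nrow(geno)
  chrs <- list()
  for (cc in unique(map$chr)) {
    sel <- which(map$chr == cc)
    mpos <- map$pos[sel]
    grid <- sort(unique(round(c(mpos, seq(min(mpos), max(mpos), by = step)), 8)))
    mk_at <- match(round(mpos, 8), grid)
    S <- if (cc == "X") 2L else 3L
    init <- if (S == 2L) c(.5, .5) else c(.25, .5, .25)
    P <- length(grid)
    # emissions: product over markers sharing a grid point
    emis <- vector("list", P)
    for (p in seq_len(P)) {
      E <- matrix(1, n, S)
      for (j in which(mk_at == p)) E <- E * .emission(geno[, sel[j]], n, S, error_prob)
      emis[[p]] <- E
    }
    rr <- haldane_r(diff(grid))
    trans <- lapply(rr, if (S == 2L) .trans_x else .trans_f2)
    alpha <- array(0, c(n, P, S))
    a <- sweep(emis[[1]], 2, init, `*`)
    alpha[, 1, ] <- a / rowSums(a)
    for (p in seq_len(P - 1)) {
      a <- (.slab(alpha, p) %*% trans[[p]]) * emis[[p + 1]]
      alpha[, p + 1, ] <- a / rowSums(a)
    }
    beta <- array(0, c(n, P, S))
    beta[, P, ] <- 1
    if (P > 1) for (p in seq(P - 1, 1)) {
      b <- (.slab(beta, p + 1) * emis[[p + 1]]) %*% t(trans[[p]])
      beta[, p, ] <- b / rowSums(b)
    }
    post <- alpha * beta
    tot <- apply(post, c(1, 2), sum)
    for (s in seq_len(S)) post[, , s] <- post[, , s] / tot
    chrs[[cc]] <- list(pos = grid, states = S, post = post, alpha = alpha,
                       trans = trans, marker_at = mk_at,
                       markers = map$marker[sel])
  }
  grid <- do.call(rbind, lapply(names(chrs), function(cc) {
    data.frame(chr = cc, pos = chrs[[cc]]$pos,
               is_x = cc == "X", stringsAsFactors = FALSE)
  }))
  structure(list(chrs = chrs, grid = grid, map = map, step = step,
                 error_prob = error_prob, n = n,
                 ids = rownames(pop$geno)),
            class = "genoprob")
}

#' @export
print.genoprob <- function(x, ...) {
  cat("Genotype probabilities:", x$n, "individuals,",
      nrow(x$grid), "grid positions on",
      length(x$chrs), "chromosome(s), step", x$step, "cM, eps =",
      x$error_prob, "\n")
  invisible(x)
}

# sample one categorical draw per row from an n x S weight matrix
.sample_rows <- function(W) {
  S <- ncol(W)
  cs <- W[, 1]
  u <- stats::runif(nrow(W)) * rowSums(W)
  out <- rep(1L, nrow(W))
  for (s in seq_len(S - 1)) {
    out <- out + (u > cs)
    if (s < S - 1) cs <- cs + W[, s + 1]
  }
  out
}

#' Multiple imputation of complete genotypes
#'
#' Draws `M` complete genotype paths per individual from the HMM
#' posterior by backward sampling of whole-chromosome paths (joint draws,
#' not independent per-position draws).
#'
#' @param probs A `genoprob` object.
#' @param M Number of imputations (the study used 256).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return Object of class `imputation_set`: integer array
#'   `n x positions x M` (autosomes 1/2/3 = AA/AB/BB; X 1/2 = hemizygous
#'   A/B) plus the grid table.
#' @export
impute_genotypes <- function(probs, M = 256, seed = NULL) {
  stopifnot(inherits(probs, "genoprob"), M >= 1)
  n <- probs$n
  G <- nrow(probs$grid)
  with_seed(seed, {
    draws <- array(NA_integer_, c(n, G, M))
    off <- 0L
    for (cc in names(probs$chrs)) {
      ch <- probs$chrs[[cc]]
      P <- length(ch$pos)
      for (m in seq_len(M)) {
        s <- .sample_rows(.slab(ch$alpha, P))
        draws[, off + P, m] <- s
        if (P > 1) for (p in seq(P - 1, 1)) {
          Tm <- ch$trans[[p]]
          # weight of state a: alpha[i, p, a] * T[a, s_i]
          Wn <- .slab(ch$alpha, p) * t(Tm[, s, drop = FALSE])
          s <- .sample_rows(Wn)
          draws[, off + p, m] <- s
        }
      }
      off <- off + P
    }
    structure(list(geno = draws, grid = probs$grid, M = as.integer(M),
                   n = n, ids = probs$ids, seed = seed,
                   map = probs$map, step = probs$step),
              class = "imputation_set")
  })
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: M =", x$M, "draws,", x$n, "individuals,",
      nrow(x$grid), "grid positions\n")
  invisible(x)
}
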