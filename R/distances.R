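## Sequence distance estimation.
##
## Alignments are stored as integer matrices (taxa x columns) with 0 for gaps
## and ambiguity codes, which are excluded pairwise ("pairwise deletion").
## DNA symbols map to 1:4 = A,C,G,T; proteins to 1:20 in BLOSUM62 row order.

.dna_symbols <- c("A", "C", "G", "T")
.aa_symbols <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## BLOSUM62 amino-acid background frequencies (Henikoff marginals), used to
## normalise the expected pairwise score in the score-based protein distance.
.aa_background <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073)

## Scoredist calibration factor for BLOSUM62
.scoredist_scale <- 1.337

#' Construct an alignment object
#'
#' @param seqs named character vector of equal-length sequences, or a
#'   character matrix (rows = taxa) of single characters.
#' @param alphabet `"dna"` or `"protein"`.
#' @return An `alignment` object: a list with an integer matrix `mat`
#'   (0 = gap/ambiguity), `labels`, `alphabet` and `symbols`.
#' @export
alignment <- function(seqs, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  symbols <- if (alphabet == "dna") .dna_symbols else .aa_symbols
  if (is.matrix(seqs)) {
    chmat <- toupper(seqs)
    labels <- rownames(seqs)
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
    chmat <- t(vapply(toupper(seqs), function(s) strsplit(s, "")[[1L]],
                      character(lens[1L])))
    labels <- names(seqs)
  }
  if (is.null(labels) || anyDuplicated(labels)) stop("labels must be unique and present")
  if (ncol(chmat) < 1L) stop("alignment must have at least one column")
  mat <- matrix(match(chmat, symbols, nomatch = 0L), nrow(chmat), ncol(chmat))
  if (alphabet == "dna") mat[chmat == "U"] <- 0L  # treat RNA/ambiguity as gaps
  rownames(mat) <- labels
  structure(list(mat = mat, labels = labels, alphabet = alphabet,
                 symbols = symbols), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", nrow(x$mat), x$alphabet, "sequences x", ncol(x$mat),
      "columns\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln an `alignment`.
#' @return Integer column count.
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Read a (possibly gapped) FASTA alignment
#'
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return An `alignment`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  alignment(seqs, alphabet)
}

#' Write an alignment as FASTA
#' @param aln an `alignment`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(aln, path) {
  ch <- matrix("-", nrow(aln$mat), ncol(aln$mat))
  ch[aln$mat > 0L] <- aln$symbols[aln$mat[aln$mat > 0L]]
  lines <- character(2L * nrow(ch))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$labels)
  lines[c(FALSE, TRUE)] <- apply(ch, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Supports the plain square format: a first line with the number of taxa,
#' then one row per taxon (`label d1 d2 ... dn`), possibly wrapped.
#'
#' @param path file path.
#' @return A symmetric numeric matrix with taxon dimnames.
#' @export
read_phylip_dist <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  n <- suppressWarnings(as.integer(toks[1L]))
  if (is.na(n) || n < 3L) stop("not a PHYLIP distance matrix: ", path)
  toks <- toks[-1L]
  if (length(toks) != n * (n + 1L)) stop("unexpected token count in ", path)
  m <- matrix(toks, nrow = n, byrow = TRUE)
  labels <- m[, 1L]
  D <- matrix(as.numeric(m[, -1L, drop = FALSE]), n, n,
              dimnames = list(labels, labels))
  if (anyNA(D)) stop("non-numeric distance entries in ", path)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  D
}

## p-distance on integer-coded rows: mismatch fraction over columns where
## both rows are non-gap. Returns c(p, usable_sites).
p_distance_idx <- function(mat, i, j) {
  a <- mat[i, ]; b <- mat[j, ]
  ok <- a > 0L & b > 0L
  n_ok <- sum(ok)
  if (n_ok == 0L) return(c(NA_real_, 0))
  c(sum(a[ok] != b[ok]) / n_ok, n_ok)
}

#' Pairwise mismatch fraction with pairwise deletion
#'
#' Columns where either sequence carries a gap or ambiguity code are excluded.
#'
#' @param seq_a,seq_b equal-length character strings (or character vectors of
#'   single characters).
#' @param alphabet `"dna"` or `"protein"`.
#' @return A list with `p` (mismatch fraction; `NA` if no usable site) and
#'   `usable` (number of compared columns).
#' @export
p_distance <- function(seq_a, seq_b, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  aln <- alignment(c(a = paste(seq_a, collapse = ""),
                     b = paste(seq_b, collapse = "")), alphabet)
  r <- p_distance_idx(aln$mat, 1L, 2L)
  list(p = r[1L], usable = as.integer(r[2L]))
}

#' Log-corrected Jukes-Cantor distance
#'
#' `d = -(3/4) log(1 - (4/3) p)` for mismatch fraction `p`; values of `p` at
#' or beyond the saturation point (>= 0.7499) return the saturation cap.
#'
#' @param p mismatch fraction(s) in `[0, 1]`.
#' @param cap saturation cap in substitutions/site.
#' @return Distance(s) in substitutions/site.
#' @export
jc_distance <- function(p, cap = 10) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  d <- rep.int(cap, length(p))
  ok <- !is.na(p) & p < 0.7499
  d[ok] <- pmin(-0.75 * log1p(-4 * p[ok] / 3), cap)
  d
}

## expected BLOSUM62 score per aligned position under background frequencies
.scoredist_state <- new.env(parent = emptyenv())
scoredist_params <- function() {
  if (is.null(.scoredist_state$B)) {
    B <- get_blosum62()[.aa_symbols, .aa_symbols]
    q <- .aa_background / sum(.aa_background)
    .scoredist_state$B <- B
    .scoredist_state$expected <- drop(q %*% B %*% q)
  }
  .scoredist_state
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

## score-based protein distance on integer-coded rows
scoredist_idx <- function(mat, i, j, cap = 10) {
  sp <- scoredist_params()
  a <- mat[i, ]; b <- mat[j, ]
  ok <- a > 0L & b > 0L
  l <- sum(ok)
  if (l == 0L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  B <- sp$B
  sigma <- sum(B[cbind(a, b)])
  sigma_r <- l * sp$expected
  sigma_u <- (sum(B[cbind(a, a)]) + sum(B[cbind(b, b)])) / 2
  num <- sigma - sigma_r
  den <- sigma_u - sigma_r
  if (!is.finite(num) || !is.finite(den) || den <= 0 || num <= 0) return(cap)
  min(cap, -.scoredist_scale * log(num / den))
}

#' Score-matrix protein distance (Scoredist-style, BLOSUM62)
#'
#' The BLOSUM62 alignment score is normalised by its expectation under the
#' BLOSUM62 background frequencies and by the mean self-score of the two
#' sequences, and converted to an evolutionary distance
#' `d = -c log((sigma - sigma_r) / (sigma_u - sigma_r))` with calibration
#' factor `c = 1.337`. Gapped or ambiguous columns are excluded pairwise.
#'
#' @param seq_a,seq_b equal-length protein sequences (strings).
#' @param cap saturation cap in substitutions/site.
#' @return Distance in substitutions/site (0 for identical sequences).
#' @export
scoredist <- function(seq_a, seq_b, cap = 10) {
  aln <- alignment(c(a = paste(seq_a, collapse = ""),
                     b = paste(seq_b, collapse = "")), "protein")
  d <- scoredist_idx(aln$mat, 1L, 2L, cap = cap)
  if (is.na(d)) stop("no usable (ungapped) sites shared by the two sequences")
  d
}

## ---- distance cache ----

#' Memoized pairwise distance cache over an alignment
#'
#' Distances are computed on first request and cached in a symmetric matrix;
#' repeat queries perform no sequence scan. Pairs with no shared ungapped
#' column are incomparable and return the saturation cap with a warning.
#'
#' @param aln an `alignment`, or `NULL` when `model = "precomputed"`.
#' @param model `"jc"` (nucleotide, log-corrected Jukes-Cantor),
#'   `"scoredist"` (protein), or `"precomputed"`.
#' @param D for `model = "precomputed"`, a symmetric labelled distance matrix
#'   (e.g. from [read_phylip_dist()]).
#' @param cap saturation cap in substitutions/site.
#' @return A `distance_cache` environment.
#' @export
distance_cache <- function(aln = NULL, model = c("jc", "scoredist", "precomputed"),
                           D = NULL, cap = 10) {
  model <- match.arg(model)
  ca <- new.env(parent = emptyenv())
  ca$model <- model
  ca$cap <- cap
  ca$n_computed <- 0L
  if (model == "precomputed") {
    stopifnot(is.matrix(D), !is.null(rownames(D)))
    if (max(abs(D - t(D))) > 1e-8) stop("precomputed matrix is not symmetric")
    ca$labels <- rownames(D)
    ca$D <- unname(D)
    diag(ca$D) <- 0
  } else {
    stopifnot(inherits(aln, "alignment"))
    if (model == "jc" && aln$alphabet != "dna")
      stop("jc model requires a DNA alignment")
    if (model == "scoredist" && aln$alphabet != "protein")
      stop("scoredist model requires a protein alignment")
    ca$labels <- aln$labels
    ca$mat <- aln$mat
    ca$tmat <- t(aln$mat)  # sites x taxa: column access is contiguous
    ## pairwise memo as a hashed environment keyed by "lo_hi"; avoids the
    ## full-matrix copy that complex assignment into an environment field
    ## would trigger on every write
    ca$memo <- new.env(parent = emptyenv(), size = 4096L)
  }
  class(ca) <- c("distance_cache", "environment")
  ca
}

## distance between taxon indices, computing+memoizing on demand
cache_dist_idx <- function(ca, i, j) {
  if (i == j) return(0)
  if (!is.null(ca$D)) return(ca$D[i, j])
  key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
  memo <- ca$memo
  d <- memo[[key]]
  if (!is.null(d)) return(d)
  d <- compute_pair(ca, i, j)
  memo[[key]] <- d
  ca$n_computed <- ca$n_computed + 1L
  d
}

compute_pair <- function(ca, i, j) {
  if (ca$model == "jc") {
    tm <- ca$tmat
    a <- tm[, i]; b <- tm[, j]
    ok <- a > 0L & b > 0L
    n_ok <- sum(ok)
    r <- if (n_ok == 0L) c(NA_real_, 0) else c(sum(a != b & ok) / n_ok, n_ok)
    if (r[2L] == 0) {
      warning("no comparable sites for pair (", ca$labels[i], ", ",
              ca$labels[j], "); using saturation cap")
      return(ca$cap)
    }
    jc_distance(r[1L], cap = ca$cap)
  } else {
    d <- scoredist_idx(ca$mat, i, j, cap = ca$cap)
    if (is.na(d)) {
      warning("no comparable sites for pair (", ca$labels[i], ", ",
              ca$labels[j], "); using saturation cap")
      return(ca$cap)
    }
    d
  }
}

## vectorized lookup/fill for index pair vectors; returns numeric vector
cache_dist_many <- function(ca, iv, jv) {
  if (!is.null(ca$D)) return(ca$D[cbind(iv, jv)])
  lo <- pmin(iv, jv); hi <- pmax(iv, jv)
  keys <- paste0(lo, "_", hi)
  memo <- ca$memo
  n <- length(keys)
  d <- numeric(n)
  miss <- integer(n); nm <- 0L
  for (t in seq_len(n)) {
    if (lo[t] == hi[t]) next
    v <- memo[[keys[t]]]
    if (is.null(v)) { nm <- nm + 1L; miss[nm] <- t; next }
    d[t] <- v
  }
  if (nm > 0L) {
    miss <- miss[seq_len(nm)]
    mk <- keys[miss]
    first <- !duplicated(mk)
    mi <- miss[first]
    vals <- if (ca$model == "jc") {
      compute_pairs_jc(ca, lo[mi], hi[mi])
    } else {
      vapply(seq_along(mi), function(t) compute_pair(ca, lo[mi[t]], hi[mi[t]]),
             0)
    }
    for (t in seq_along(mi)) memo[[mk[first][t]]] <- vals[t]
    d[miss] <- vals[match(mk, mk[first])]
    ca$n_computed <- ca$n_computed + length(mi)
  }
  d
}

## batched Jukes-Cantor distances for index pair vectors (one matrix pass)
compute_pairs_jc <- function(ca, iv, jv) {
  tm <- ca$tmat
  A <- tm[, iv, drop = FALSE]
  B <- tm[, jv, drop = FALSE]
  ok <- A > 0L & B > 0L
  n_ok <- colSums(ok)
  mism <- colSums((A != B) & ok)
  p <- mism / n_ok   # NaN when no comparable site -> saturation cap
  if (any(n_ok == 0L)) {
    p[n_ok == 0L] <- NA_real_
    warning("pairs with no comparable sites; using saturation cap")
  }
  jc_distance(p, cap = ca$cap)
}

## Precompute the full pairwise Jukes-Cantor matrix with one-hot
## crossproducts (BLAS); afterwards every lookup is a plain matrix read.
## Worth it when most pairs will eventually be requested (full builds).
cache_precompute_all <- function(ca) {
  if (!is.null(ca$D)) return(invisible(ca))
  if (ca$model != "jc")
    stop("full precomputation is implemented for the jc model only")
  mat <- ca$mat
  V <- (mat > 0L) * 1
  valid <- tcrossprod(V)
  matches <- matrix(0, nrow(mat), nrow(mat))
  for (k in seq_along(.dna_symbols))
    matches <- matches + tcrossprod((mat == k) * 1)
  p <- 1 - matches / valid  # NaN where valid == 0
  if (any(valid == 0 & upper.tri(valid)))
    warning("pairs with no comparable sites; using saturation cap")
  D <- matrix(jc_distance(as.vector(p), cap = ca$cap), nrow(mat), nrow(mat))
  diag(D) <- 0
  ca$D <- D
  invisible(ca)
}

#' Cached pairwise distance between two taxa
#'
#' @param cache a [distance_cache()].
#' @param i,j taxon labels.
#' @return Distance in substitutions/site.
#' @export
get_distance <- function(cache, i, j) {
  ii <- match(i, cache$labels); jj <- match(j, cache$labels)
  if (is.na(ii) || is.na(jj))
    stop("unknown taxon: ", paste(c(i, j)[c(is.na(ii), is.na(jj))], collapse = ", "))
  if (ii == jj) return(0)
  cache_dist_idx(cache, ii, jj)
}

## full distance matrix over a subset of taxon indices (filling the cache)
cache_dist_matrix <- function(ca, idx) {
  m <- length(idx)
  D <- matrix(0, m, m, dimnames = list(ca$labels[idx], ca$labels[idx]))
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    D[a, b] <- D[b, a] <- cache_dist_idx(ca, idx[a], idx[b])
  }
  D
}
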