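#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(out) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  out
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis via Fisher's exact test
#'
#' Per gene set, builds the 2x2 table of set membership against selection on
#' the background universe and applies a two-sided Fisher exact test, with
#' BH-FDR across sets. Sets are intersected with the background first and
#' filtered to `[min_size, max_size]`; sets disjoint from the background are
#' skipped with a reason.
#'
#' @param selected character vector of selected ids (must be within
#'   `background`).
#' @param background character vector, the tested universe.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param min_size,max_size set-size bounds after background intersection
#'   (defaults 2 and 500).
#' @return data.frame: `set`, `k_overlap`, `n_selected`, `K_set`,
#'   `N_background`, `odds_ratio`, `p`, `fdr`, `skipped`.
#' @export
fisher_ora <- function(selected, background, sets, min_size = 2, max_size = 500) {
  selected <- unique(selected); background <- unique(background)
  offenders <- setdiff(selected, background)
  if (length(offenders))
    stop(sprintf("selected ids not in background: %s",
                 paste(offenders, collapse = ", ")), call. = FALSE)
  N <- length(background); n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), background)
    K <- length(members)
    rec <- data.frame(set = nm, k_overlap = NA_integer_, n_selected = n,
                      K_set = K, N_background = N, odds_ratio = NA_real_,
                      p = NA_real_, skipped = NA_character_,
                      stringsAsFactors = FALSE)
    if (K == 0) { rec$skipped <- "disjoint from background"; return(rec) }
    if (K < min_size || K > max_size) { rec$skipped <- "size out of bounds"; return(rec) }
    k <- length(intersect(members, selected))
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2, 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    rec$k_overlap <- k
    rec$odds_ratio <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
    rec$p <- ft$p.value
    rec
  })
  df <- do.call(rbind, rows)
  df$fdr <- NA_real_
  ok <- !is.na(df$p)
  if (any(ok)) df$fdr[ok] <- bh_fdr(df$p[ok])
  df[, c("set", "k_overlap", "n_selected", "K_set", "N_background",
         "odds_ratio", "p", "fdr", "skipped")]
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# Hit increments |score|^w / sum(|score|^w over hits); miss decrements 1/(N-K).
# ES is the extreme deviation of the running sum from zero.
gsea_es <- function(scores_sorted, hit_idx, weight = 1) {
  N <- length(scores_sorted)
  K <- length(hit_idx)
  inc <- numeric(N)
  w <- abs(scores_sorted[hit_idx])^weight
  if (sum(w) == 0) w <- rep(1, K)  # all-zero scores: unweighted KS
  inc[hit_idx] <- w / sum(w)
  miss <- rep(1 / (N - K), N)
  miss[hit_idx] <- 0
  run <- cumsum(inc - miss)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment (weighted KS running sum)
#'
#' Computes the classic weighted Kolmogorov-Smirnov enrichment score on a
#' ranked list (hit increments proportional to `|score|^weight`, miss
#' decrements `1/(N-K)`), with gene-label permutation for significance:
#' the normalized score is `ES / mean(|permutation ES| of matching sign)` and
#' the permutation p carries a +1 pseudocount. `perm = "exhaustive"`
#' enumerates every size-K gene subset (feasible for small N) instead of
#' sampling.
#'
#' @param scores named numeric vector of ranking statistics (ids unique,
#'   values finite); sorted decreasingly internally.
#' @param sets named list of gene sets.
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed optional integer seed for the permutations.
#' @param weight running-sum weight exponent (default 1).
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked ids.
#' @param perm `"sample"` (default) or `"exhaustive"`.
#' @return data.frame: `set`, `size`, `es`, `nes`, `perm_p`, `skipped`.
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, seed = NULL,
                           weight = 1, min_size = 2, max_size = 500,
                           perm = c("sample", "exhaustive")) {
  perm <- match.arg(perm)
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (anyDuplicated(names(scores))) stop("duplicate ids in scores", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  ids <- names(s)
  N <- length(s)

  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), ids)
    K <- length(members)
    rec <- data.frame(set = nm, size = K, es = NA_real_, nes = NA_real_,
                      perm_p = NA_real_, skipped = NA_character_,
                      stringsAsFactors = FALSE)
    if (K < min_size || K > max_size) { rec$skipped <- "size out of bounds"; return(rec) }
    if (K == N) { rec$skipped <- "set covers all ranked genes"; return(rec) }
    hit_idx <- which(ids %in% members)
    es <- gsea_es(s, hit_idx, weight)
    if (perm == "exhaustive") {
      combos <- utils::combn(N, K)
      perm_es <- apply(combos, 2, function(ix) gsea_es(s, ix, weight))
    } else {
      perm_es <- vapply(seq_len(n_perm), function(i)
        gsea_es(s, sort(sample.int(N, K)), weight), numeric(1))
    }
    same_sign <- perm_es[sign(perm_es) == sign(es)]
    rec$es <- es
    rec$nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    extreme <- if (es >= 0) perm_es >= es else perm_es <= es
    rec$perm_p <- (1 + sum(extreme)) / (length(perm_es) + 1)
    rec
  })
  do.call(rbind, rows)
}

#' Directional sign-concordance between two effect tables
#'
#' Counts matched ids whose effect signs agree and tests the concordant
#' fraction against `null_prop` with a two-sided exact binomial test
#' (point-probability method: the p-value sums all outcome probabilities no
#' larger than that of the observed count). Ids with a zero effect in either
#' table are excluded and counted.
#'
#' @param effects_a,effects_b named numeric vectors of signed effects
#'   (log-HRs, betas, ...).
#' @param null_prop null concordance probability (default 0.5).
#' @return list: `n`, `k_concordant`, `prop`, `p_two_sided`, `n_zero_dropped`.
#' @export
sign_concordance <- function(effects_a, effects_b, null_prop = 0.5) {
  ids <- intersect(names(effects_a), names(effects_b))
  if (!length(ids)) stop("no matched ids between the two effect tables", call. = FALSE)
  a <- effects_a[ids]; b <- effects_b[ids]
  nonzero <- a != 0 & b != 0 & !is.na(a) & !is.na(b)
  n_zero <- sum(!nonzero)
  a <- a[nonzero]; b <- b[nonzero]
  n <- length(a)
  if (!n) stop("no non-zero matched effects", call. = FALSE)
  k <- sum(sign(a) == sign(b))
  bt <- stats::binom.test(k, n, p = null_prop, alternative = "two.sided")
  list(n = n, k_concordant = k, prop = k / n, p_two_sided = bt$p.value,
       n_zero_dropped = n_zero)
}

#' Build a protein-protein interaction graph from an edge list
#'
#' Undirected, deduplicated (both orientations collapse), self-loops removed.
#'
#' @param edges two-column data.frame or matrix of protein ids.
#' @return list of class `ppi_graph` with `edges` (canonical two-column
#'   data.frame) and `n_edges`.
#' @export
ppi_graph <- function(edges) {
  e <- as.data.frame(edges, stringsAsFactors = FALSE)[, 1:2]
  names(e) <- c("a", "b")
  e$a <- as.character(e$a); e$b <- as.character(e$b)
  e <- e[e$a != e$b, , drop = FALSE]
  lo <- pmin(e$a, e$b); hi <- pmax(e$a, e$b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  e <- data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
  structure(list(edges = e, n_edges = nrow(e)), class = "ppi_graph")
}

#' First-degree interaction partners of a seed set
#'
#' Union of the graph neighbors of every seed, minus the seeds themselves
#' (seeds that are also partners of other seeds are reported separately).
#' Seeds absent from the graph contribute nothing.
#'
#' @param seeds character vector of seed protein ids.
#' @param graph a [ppi_graph()].
#' @return list: `partners` (sorted), `seeds_interacting` (seeds that are
#'   neighbors of other seeds, sorted), `seeds_absent`.
#' @export
first_degree_partners <- function(seeds, graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  seeds <- unique(as.character(seeds))
  e <- graph$edges
  nodes <- unique(c(e$a, e$b))
  nb <- c(e$b[e$a %in% seeds], e$a[e$b %in% seeds])
  nb <- unique(nb)
  list(partners = sort(setdiff(nb, seeds)),
       seeds_interacting = sort(intersect(nb, seeds)),
       seeds_absent = sort(setdiff(seeds, nodes)))
}
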