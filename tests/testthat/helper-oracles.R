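# Independent oracles used to cross-check the package implementations.
# These deliberately use naive, separate code paths (and Biostrings
# translation tables directly) so they do not share logic with the package.

oracle_code <- function(id) Biostrings::getGeneticCode(as.character(id))

# brute-force pathway enumeration: recursively walk every ordering of the
# differing positions, classifying each step by translation, and average the
# (syn, nonsyn) step counts over pathways avoiding intermediate stops
oracle_pathway_average <- function(from, to, code) {
  f <- strsplit(from, "")[[1]]
  t <- strsplit(to, "")[[1]]
  diffs <- which(f != t)
  if (length(diffs) == 0) return(c(syn = 0, nonsyn = 0))
  results <- list()
  walk <- function(cur, remaining, syn, nonsyn, hit_stop) {
    if (length(remaining) == 0) {
      results[[length(results) + 1]] <<- c(syn, nonsyn, hit_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- t[p]
      codon_nxt <- paste(nxt, collapse = "")
      step_syn <- code[[paste(cur, collapse = "")]] == code[[codon_nxt]]
      is_stop <- code[[codon_nxt]] == "*" && codon_nxt != to
      walk(nxt, setdiff(remaining, p),
           syn + step_syn, nonsyn + !step_syn, hit_stop || is_stop)
    }
  }
  walk(f, diffs, 0, 0, FALSE)
  m <- do.call(rbind, results)
  usable <- m[, 3] == 0
  if (!any(usable)) usable <- rep(TRUE, nrow(m))
  c(syn = mean(m[usable, 1]), nonsyn = mean(m[usable, 2]))
}

# naive double-loop diversity statistics on a character matrix with NAs
oracle_pi <- function(mat) {
  total <- 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    obs <- which(!is.na(col))
    nc <- length(obs)
    if (nc < 2) next
    diffs <- 0
    for (a in seq_len(nc - 1)) {
      for (b in (a + 1):nc) {
        if (col[obs[a]] != col[obs[b]]) diffs <- diffs + 1
      }
    }
    total <- total + diffs / choose(nc, 2)
  }
  total
}

oracle_S <- function(mat) {
  s <- 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[!is.na(mat[, j]), j]
    if (length(unique(col)) >= 2) s <- s + 1
  }
  s
}

oracle_tajima_d <- function(mat) {
  n <- nrow(mat)
  S <- oracle_S(mat)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (oracle_pi(mat) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# naive per-pair LD from an explicit haplotype contingency table
oracle_ld_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  ax <- sort(unique(x)); ay <- sort(unique(y))
  if (length(ax) != 2 || length(ay) != 2) return(NULL)
  n11 <- sum(x == ax[1] & y == ay[1])
  n <- length(x)
  pA <- mean(x == ax[1]); pB <- mean(y == ay[1])
  D <- n11 / n - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(d_prime_abs = if (D == 0) 0 else abs(D / dmax),
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       four = length(unique(paste(x, y))) == 4)
}

# independent straightforward coalescent simulator: explicit node lists,
# recursion for descendant sets, mutations via rejection on cumulative
# lengths -- structured differently from the package implementation
oracle_coalescent_matrix <- function(n, S) {
  id <- seq_len(n)
  children <- vector("list", 2 * n - 1)
  height <- numeric(2 * n - 1)
  live <- id
  t <- 0
  nxt <- n
  while (length(live) > 1) {
    k <- length(live)
    t <- t + rexp(1, rate = choose(k, 2))
    pick <- sample(seq_along(live), 2)
    nxt <- nxt + 1
    children[[nxt]] <- live[pick]
    height[nxt] <- t
    live <- c(live[-pick], nxt)
  }
  desc <- function(v) {
    if (v <= n) return(v)
    unlist(lapply(children[[v]], desc))
  }
  parent <- rep(NA_integer_, 2 * n - 1)
  for (v in (n + 1):(2 * n - 1)) parent[children[[v]]] <- v
  nodes <- which(!is.na(parent))
  lens <- height[parent[nodes]] - height[nodes]
  mat <- matrix(0L, n, S)
  if (S > 0) {
    hit <- sample(length(nodes), S, replace = TRUE, prob = lens)
    for (s in seq_len(S)) mat[desc(nodes[hit[s]]), s] <- 1L
  }
  mat
}

# convert a 0/1 haplotype matrix to an A/G nucleotide matrix (0 = ancestral
# A) for use with the nucleotide-level statistics
binary_to_bases <- function(X) {
  out <- matrix(ifelse(X == 1L, "G", "A"), nrow(X))
  rownames(out) <- sprintf("h%02d", seq_len(nrow(X)))
  out
}

random_base_matrix <- function(n, L, missing_rate = 0.05) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n)
  mat[matrix(runif(n * L) < missing_rate, n)] <- NA_character_
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  mat
}
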