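# Brute-force oracles: explicit loops over haplotype pairs and sites,
# independent of the package's vectorized implementations.

random_gm <- function(n_hap = 10, S = 20, L = 1000, miss = 0.1,
                      pops = NULL) {
  if (is.null(pops)) pops <- rep(c("popA", "popB"), each = ceiling(n_hap / 2))[seq_len(n_hap)]
  al <- matrix(rbinom(n_hap * S, 1L, runif(S, 0.1, 0.9)), n_hap, S,
               byrow = TRUE)
  if (miss > 0) al[runif(n_hap * S) < miss] <- NA_integer_
  pos <- sort(sample.int(L, S))
  genotype_matrix(al, pos, L, pops)
}

counted_sites <- function(al) {
  vapply(seq_len(ncol(al)), function(s) sum(!is.na(al[, s])) >= 2L,
         logical(1))
}

# pi via all haplotype pairs at each counted site
oracle_pi_sum <- function(al) {
  tot <- 0
  for (s in which(counted_sites(al))) {
    x <- al[!is.na(al[, s]), s]
    n <- length(x)
    cnt <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      cnt <- cnt + (x[i] != x[j])
    tot <- tot + cnt / choose(n, 2)
  }
  unname(tot)
}

oracle_thetaw_sum <- function(al) {
  tot <- 0
  for (s in which(counted_sites(al))) {
    x <- al[!is.na(al[, s]), s]
    if (length(unique(x)) > 1L) tot <- tot + 1 / sum(1 / seq_len(length(x) - 1))
  }
  unname(tot)
}

oracle_dxy_sum <- function(alA, alB) {
  tot <- 0
  for (s in seq_len(ncol(alA))) {
    a <- alA[!is.na(alA[, s]), s]
    b <- alB[!is.na(alB[, s]), s]
    if (length(a) < 2L || length(b) < 2L) next
    cnt <- 0
    for (i in seq_along(a)) for (j in seq_along(b)) cnt <- cnt + (a[i] != b[j])
    tot <- tot + cnt / (length(a) * length(b))
  }
  unname(tot)
}

oracle_fst_hudson <- function(alA, alB) {
  hw <- hb <- 0
  for (s in seq_len(ncol(alA))) {
    a <- alA[!is.na(alA[, s]), s]
    b <- alB[!is.na(alB[, s]), s]
    if (length(a) < 2L || length(b) < 2L) next
    pw <- function(x) {
      cnt <- 0
      for (i in seq_len(length(x) - 1)) for (j in (i + 1):length(x))
        cnt <- cnt + (x[i] != x[j])
      cnt / choose(length(x), 2)
    }
    cnt <- 0
    for (i in seq_along(a)) for (j in seq_along(b)) cnt <- cnt + (a[i] != b[j])
    hw <- hw + (pw(a) + pw(b)) / 2
    hb <- hb + cnt / (length(a) * length(b))
  }
  if (hb > 0) unname(1 - hw / hb) else NA_real_
}

# site-wise D and fdM with explicit per-site branching
oracle_d_fdm <- function(gm, p1, p2, p3, p4) {
  freq <- function(pop, s) {
    x <- gm$alleles[gm$pops == pop, s]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    mean(x)
  }
  abba <- baba <- num <- den <- 0
  for (s in seq_len(ncol(gm$alleles))) {
    f <- c(freq(p1, s), freq(p2, s), freq(p3, s), freq(p4, s))
    if (any(is.na(f))) next
    ab <- (1 - f[1]) * f[2] * f[3] * (1 - f[4])
    ba <- f[1] * (1 - f[2]) * f[3] * (1 - f[4])
    abba <- abba + ab
    baba <- baba + ba
    num <- num + ab - ba
    if (f[2] >= f[1]) {
      pd <- max(f[2], f[3])
      den <- den + ((1 - f[1]) * pd * pd * (1 - f[4]) -
                      f[1] * (1 - pd) * pd * (1 - f[4]))
    } else {
      pd <- max(f[1], f[3])
      den <- den - ((1 - pd) * f[2] * pd * (1 - f[4]) -
                      pd * (1 - f[2]) * pd * (1 - f[4]))
    }
  }
  list(d = if (abba + baba > 0) (abba - baba) / (abba + baba) else NA_real_,
       fdm = if (den != 0) num / den else NA_real_)
}

oracle_ibs <- function(gm) {
  d <- gm_dosage(gm)$dosage
  n <- nrow(d)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    vals <- c()
    for (s in seq_len(ncol(d)))
      if (!is.na(d[i, s]) && !is.na(d[j, s]))
        vals <- c(vals, 1 - abs(d[i, s] - d[j, s]) / 2)
    if (length(vals)) out[i, j] <- mean(vals)
  }
  out
}

# single-pair identity tract around a focal SNP, written as a direct scan
oracle_tract <- function(a, b, pos, L, focal, max_gap) {
  if (!is.na(a[focal]) && !is.na(b[focal]) && a[focal] != b[focal]) return(0)
  mism <- function(k) !is.na(a[k]) && !is.na(b[k]) && a[k] != b[k]
  lb <- 0
  k <- focal
  repeat {
    if (k == 1) break
    if (pos[k] - pos[k - 1] > max_gap) { lb <- pos[k]; break }
    if (mism(k - 1)) { lb <- pos[k - 1]; break }
    k <- k - 1
  }
  rb <- L
  k <- focal
  repeat {
    if (k == length(pos)) break
    if (pos[k + 1] - pos[k] > max_gap) { rb <- pos[k]; break }
    if (mism(k + 1)) { rb <- pos[k + 1]; break }
    k <- k + 1
  }
  rb - lb
}

oracle_hscan <- function(gm, focal, max_gap = 1e5) {
  al <- gm$alleles
  n <- nrow(al)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, oracle_tract(al[i, ], al[j, ], gm$positions,
                                 gm$seq_length, focal, max_gap))
  mean(vals)
}

# independent quartet caller: prune with ape, root at the outgroup tip,
# read the cherry not involving the outgroup
oracle_quartet <- function(tree, tips) {
  q <- ape::keep.tip(tree, unname(tips))
  q <- ape::unroot(q)
  parts <- ape::prop.part(ape::root(q, outgroup = tips[["outgroup"]],
                                    resolve.root = TRUE))
  labs <- attr(parts, "labels")
  pairs <- Filter(function(p) length(p) == 2L, parts)
  pairnames <- lapply(pairs, function(p) sort(labs[p]))
  for (k in 1:3) {
    sis <- sort(unname(tips[genarch:::TOPO_PAIRS[[k]]]))
    if (any(vapply(pairnames, identical, logical(1), sis))) return(k)
  }
  NA_integer_  # unresolved
}

# fixture model used across tests
toy_model <- function(topology = 1, ne = 2e5, mig_tx = 0, mig_xb = 0,
                      t_recent = 2e5, t_deep = 8e5, t_outgroup = 9.6e6,
                      r = 0) {
  demographic_model(
    topology,
    ne = c(tapajos = ne, xingu = ne, belem = ne, anc_recent = ne,
           anc_deep = ne, outgroup = ne),
    t_recent = t_recent, t_deep = t_deep, t_outgroup = t_outgroup,
    mig = c(tapajos_xingu = mig_tx, xingu_belem = mig_xb), r = r)
}
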