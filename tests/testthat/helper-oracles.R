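# Independent brute-force oracles: literal, loop-based transcriptions of
# the descriptor and metric formulas, kept deliberately separate from the
# package's vectorized implementations. All encoder oracles recompute
# from the shipped raw tables.

AA <- bitterpep::AA_ALPHABET

random_peptide <- function(len) {
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

# two-pass standard-normal normalization (mean 0, RMS-deviation 1)
o_normalize <- function(raw) {
  m <- sum(raw) / length(raw)
  dev <- raw - m
  dev / sqrt(sum(dev^2) / length(raw))
}

o_scales <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      raw <- bitterpep::aa_scales(normalized = FALSE)
      cache <<- lapply(raw, o_normalize)
    }
    cache
  }
})

# three-property correlation, term by term
o_theta <- function(a, b) {
  sc <- o_scales()
  ((sc$hydrophobicity[a] - sc$hydrophobicity[b])^2 +
   (sc$hydrophilicity[a] - sc$hydrophilicity[b])^2 +
   (sc$side_chain_mass[a] - sc$side_chain_mass[b])^2) / 3
}

o_aac <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  out <- setNames(numeric(20), AA)
  for (ch in s) out[ch] <- out[ch] + 1
  out / length(s)
}

o_tpaac <- function(seq, lambda = 1, omega = 0.05) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  f <- o_aac(seq)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(n - j)) acc <- acc + o_theta(s[i], s[i + j])
    theta[j] <- acc / (n - j)
  }
  denom <- sum(f) + omega * sum(theta)
  c(f / denom, setNames(omega * theta / denom, paste0("lambda", 1:lambda)))
}

o_apaac <- function(seq, lambda = 1, w = 0.5) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  sc <- o_scales()
  f <- o_aac(seq)
  tau <- numeric(2 * lambda)
  for (a in seq_len(lambda)) {
    a1 <- 0; a2 <- 0
    for (i in seq_len(n - a)) {
      a1 <- a1 + sc$hydrophobicity[s[i]] * sc$hydrophobicity[s[i + a]]
      a2 <- a2 + sc$hydrophilicity[s[i]] * sc$hydrophilicity[s[i + a]]
    }
    tau[2 * a - 1] <- a1 / (n - a)
    tau[2 * a] <- a2 / (n - a)
  }
  denom <- sum(f) + w * sum(tau)
  nm <- as.vector(rbind(paste0("H1.lag", 1:lambda), paste0("H2.lag", 1:lambda)))
  c(f / denom, setNames(w * tau / denom, nm))
}

o_pair_names <- function(alphabet = AA) {
  out <- character(0)
  for (a in alphabet) for (b in alphabet) out <- c(out, paste0(a, b))
  out
}

o_asdc <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  out <- setNames(numeric(400), o_pair_names())
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    key <- paste0(s[i], s[j])
    out[key] <- out[key] + 1
  }
  out / (n * (n - 1) / 2)
}

o_dpc <- function(seq, alphabet = AA) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  out <- setNames(numeric(length(alphabet)^2), o_pair_names(alphabet))
  for (i in 1:(n - 1)) {
    key <- paste0(s[i], s[i + 1])
    out[key] <- out[key] + 1
  }
  out / (n - 1)
}

o_dde <- function(seq) {
  cc <- bitterpep::codon_counts()
  cn <- 61
  n <- nchar(seq)
  dc <- o_dpc(seq)
  out <- dc
  for (nm in names(dc)) {
    r <- substr(nm, 1, 1); s2 <- substr(nm, 2, 2)
    tm <- (cc[[r]] / cn) * (cc[[s2]] / cn)
    tv <- tm * (1 - tm) / (n - 1)
    out[nm] <- (dc[nm] - tm) / sqrt(tv)
  }
  out
}

o_groups <- c(G = "g1", A = "g1", V = "g1", L = "g1", M = "g1", I = "g1",
              F = "g2", Y = "g2", W = "g2",
              K = "g3", R = "g3", H = "g3",
              D = "g4", E = "g4",
              S = "g5", T = "g5", C = "g5", P = "g5", N = "g5", Q = "g5")

o_gaac <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  out <- setNames(numeric(5), paste0("g", 1:5))
  for (ch in s) out[o_groups[ch]] <- out[o_groups[ch]] + 1
  out / length(s)
}

# group codes are two characters, so count pairs via explicit translation
o_gdpc <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  g <- o_groups[s]
  n <- length(g)
  nm <- character(0)
  for (a in paste0("g", 1:5)) for (b in paste0("g", 1:5))
    nm <- c(nm, paste0(a, b))
  out <- setNames(numeric(25), nm)
  for (i in 1:(n - 1)) {
    key <- paste0(g[i], g[i + 1])
    out[key] <- out[key] + 1
  }
  out / (n - 1)
}

o_soc <- function(seq, nlag = 1) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  dm <- bitterpep::aa_distance_matrices()
  out <- numeric(0)
  for (m in names(dm)) {
    for (d in seq_len(nlag)) {
      acc <- 0
      for (i in seq_len(n - d)) acc <- acc + dm[[m]][s[i], s[i + d]]^2
      out <- c(out, setNames(acc, paste0(m, ".lag", d)))
    }
  }
  out
}

o_qso <- function(seq, nlag = 1, w = 0.1) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  dm <- bitterpep::aa_distance_matrices()
  f <- o_aac(seq)
  out <- numeric(0)
  for (m in names(dm)) {
    tau <- numeric(nlag)
    for (d in seq_len(nlag)) {
      acc <- 0
      for (i in seq_len(n - d)) acc <- acc + dm[[m]][s[i], s[i + d]]^2
      tau[d] <- acc
    }
    denom <- sum(f) + w * sum(tau)
    blk <- c(f / denom, setNames(w * tau / denom, paste0("lag", 1:nlag)))
    names(blk) <- paste0(m, ".", names(blk))
    out <- c(out, blk)
  }
  out
}

o_all <- function(seq) {
  list(AAC = o_aac(seq), TPAAC = o_tpaac(seq), APAAC = o_apaac(seq),
       ASDC = o_asdc(seq), DPC = o_dpc(seq), DDE = o_dde(seq),
       GAAC = o_gaac(seq), GDPC = o_gdpc(seq), SOCNumber = o_soc(seq),
       QSOrder = o_qso(seq))
}

# confusion-matrix arithmetic, one sample at a time
o_metrics <- function(truth, scores, threshold = 0.5) {
  TP <- FP <- TN <- FN <- 0
  for (i in seq_along(truth)) {
    call <- scores[i] >= threshold
    if (truth[i] == 1 && call) TP <- TP + 1
    if (truth[i] == 0 && call) FP <- FP + 1
    if (truth[i] == 0 && !call) TN <- TN + 1
    if (truth[i] == 1 && !call) FN <- FN + 1
  }
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       Sn = TP / (TP + FN), Sp = TN / (TN + FP),
       ACC = (TP + TN) / length(truth),
       MCC = if (den == 0) 0 else (TN * TP - FN * FP) / den)
}

# exhaustive positive/negative pair counting, ties worth 1/2
o_auroc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
  acc / (length(pos) * length(neg))
}
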