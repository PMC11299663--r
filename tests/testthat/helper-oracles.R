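# Independent brute-force oracles for the scoring engine. These carry
# their own copies of the property definitions and enumerate alignments
# with explicit loops, so they share no code path with the package.

ORACLE_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_charge <- local({
  q <- setNames(rep(0, 20), ORACLE_AA)
  q[c("D", "E")] <- -1
  q[c("K", "R")] <- 1
  q["H"] <- 0.1
  q
})

oracle_hydropathy <- local({
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
          H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
          W = -0.9, Y = -1.3)
  u <- (kd + 4.5) / 9
  u - mean(u)
})

# Score of one alignment by direct enumeration of interacting pairs:
# every CDR3 position i against antigen positions within one residue of
# the directly-aligned position. Requires the CDR3 to fit in the antigen.
naive_alignment_cs <- function(cdr3, antigen, offset, mode = "electrostatic",
                               w0 = 1, w1 = 0.5, lambda = 1) {
  cc <- strsplit(cdr3, "")[[1]]
  ac <- strsplit(antigen, "")[[1]]
  qc <- oracle_charge[cc]; qa <- oracle_charge[ac]
  hc <- oracle_hydropathy[cc]; ha <- oracle_hydropathy[ac]
  s <- 0
  for (i in seq_along(cc)) {
    center <- i + offset
    for (j in (center - 1):(center + 1)) {
      if (j < 1 || j > length(ac)) next
      w <- if (j == center) w0 else w1
      s <- s + w * (-(qc[[i]] * qa[[j]]))
      if (mode == "combo") s <- s + lambda * w * hc[[i]] * ha[[j]]
    }
  }
  s
}

# Exhaustive enumeration of all full-containment offsets; the shorter
# sequence slides within the longer. Returns the max and its first
# (smallest) offset.
naive_sliding_max <- function(cdr3, antigen, mode = "electrostatic",
                              w0 = 1, w1 = 0.5, lambda = 1) {
  if (nchar(cdr3) > nchar(antigen)) { tmp <- cdr3; cdr3 <- antigen; antigen <- tmp }
  offsets <- 0:(nchar(antigen) - nchar(cdr3))
  cs <- vapply(offsets, function(o)
    naive_alignment_cs(cdr3, antigen, o, mode, w0, w1, lambda), numeric(1))
  list(cs = max(cs), offset = offsets[which.max(cs)])
}

# Random amino-acid string; charged_boost adds extra mass on D/E/K/R.
rand_aa <- function(n, charged_boost = 0) {
  p <- rep(1, 20)
  p[ORACLE_AA %in% c("D", "E", "K", "R")] <- 1 + charged_boost
  paste(sample(ORACLE_AA, n, replace = TRUE, prob = p / sum(p)),
        collapse = "")
}

# Small clinical table with exponential times, no link to any score.
rand_clinical <- function(ids, event_frac = 0.7) {
  n <- length(ids)
  data.frame(case_id = ids, time = rexp(n, 0.01),
             event = as.integer(runif(n) < event_frac),
             stringsAsFactors = FALSE)
}
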