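# Builds the plain-text physicochemical tables shipped in inst/extdata/.
# Residue order is fixed as the alphabetical one-letter codes A,C,D,...,Y.
# Run from the package root: Rscript data-raw/make_tables.R

aa <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")

## --- per-residue scales (classic PseAAC trio) ---------------------------
# hydrophobicity: Tanford-style scale as used throughout the PseAAC lineage
# hydrophilicity: Hopp-Woods
# side_chain_mass: monoisotopic-free integer side-chain masses (Da)
hydrophobicity <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)
hydrophilicity <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
  G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
  M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
  S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
side_chain_mass <- c(
  A =  15, C =  47, D =  59, E =  73, F =  91,
  G =   1, H =  82, I =  57, K =  73, L =  57,
  M =  75, N =  58, P =  42, Q =  72, R = 101,
  S =  31, T =  45, V =  43, W = 130, Y = 107)

scales <- data.frame(residue = aa,
                     hydrophobicity = hydrophobicity[aa],
                     hydrophilicity = hydrophilicity[aa],
                     side_chain_mass = side_chain_mass[aa])
write.table(scales, "inst/extdata/aa_scales.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## --- Grantham chemical distance -----------------------------------------
# Computed from Grantham's formula
#   D(i,j) = rho * sqrt(alpha*(c_i-c_j)^2 + beta*(p_i-p_j)^2 + gamma*(v_i-v_j)^2)
# with composition c, polarity p and side-chain volume v per residue, the
# published constants alpha = 1.833, beta = 0.1018, gamma = 0.000399, and
# rho normalising the mean over the 190 unordered pairs to 100. Values are
# rounded to integers, so an entry may differ by +/-1 from some printed
# versions of the table.
gr <- rbind(
  #        c     p     v
  A = c(0.00,  8.1,  31.0),
  C = c(2.75,  5.5,  55.0),
  D = c(1.38, 13.0,  54.0),
  E = c(0.92, 12.3,  83.0),
  F = c(0.00,  5.2, 132.0),
  G = c(0.74,  9.0,   3.0),
  H = c(0.58, 10.4,  96.0),
  I = c(0.00,  5.2, 111.0),
  K = c(0.33, 11.3, 119.0),
  L = c(0.00,  4.9, 111.0),
  M = c(0.00,  5.7, 105.0),
  N = c(1.33, 11.6,  56.0),
  P = c(0.39,  8.0,  32.5),
  Q = c(0.89, 10.5,  85.0),
  R = c(0.65, 10.5, 124.0),
  S = c(1.42,  9.2,  32.0),
  T = c(0.71,  8.6,  61.0),
  V = c(0.00,  5.9,  84.0),
  W = c(0.13,  5.4, 170.0),
  Y = c(0.20,  6.2, 136.0))
alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
raw <- matrix(0, 20, 20, dimnames = list(aa, aa))
for (i in 1:20) for (j in 1:20)
  raw[i, j] <- sqrt(alpha * (gr[i, 1] - gr[j, 1])^2 +
                    beta  * (gr[i, 2] - gr[j, 2])^2 +
                    gamma * (gr[i, 3] - gr[j, 3])^2)
rho <- 100 / mean(raw[upper.tri(raw)])
grantham <- round(rho * raw)
write.table(data.frame(residue = aa, grantham, check.names = FALSE),
            "inst/extdata/grantham.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## --- synthetic physicochemical distance (Schneider-Wrede slot) ----------
# A synthetic stand-in distance matrix built from the three normalised
# scales above: d(r,s) = sqrt(mean squared difference of the normalised
# hydrophobicity, hydrophilicity and side-chain mass), rescaled so the
# largest pairwise distance is 1 (the scale on which Schneider-Wrede-type
# matrices are quoted). Symmetric with a zero diagonal by construction;
# users holding the published Schneider-Wrede matrix can drop it in via
# the same TSV layout.
znorm <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
h1 <- znorm(scales$hydrophobicity)
h2 <- znorm(scales$hydrophilicity)
m  <- znorm(scales$side_chain_mass)
sw <- matrix(0, 20, 20, dimnames = list(aa, aa))
for (i in 1:20) for (j in 1:20)
  sw[i, j] <- sqrt(((h1[i] - h1[j])^2 + (h2[i] - h2[j])^2 + (m[i] - m[j])^2) / 3)
sw <- round(sw / max(sw), 6)
write.table(data.frame(residue = aa, sw, check.names = FALSE),
            "inst/extdata/schneider_wrede_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("wrote", length(aa), "residues; grantham rho =", rho, "\n")
cat("anchor checks: d(A,R) =", grantham["A", "R"],
    " d(L,I) =", grantham["L", "I"],
    " d(C,W) =", grantham["C", "W"], "\n")
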