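# Shared constants.

# 20 standard amino acids, alphabetical by one-letter code (the order used by
# the binary, composition, CKSAAP and PSSM encoders).
AA_STANDARD20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Window position labels P8..P1 (N-terminal of the scissile bond) then
# P1'..P8' (C-terminal), Schechter-Berger notation; "p" suffix = prime.
WINDOW_POSITIONS <- c(paste0("P", 8:1), paste0("P", 1:8, "p"))

# Kyte-Doolittle hydropathy, named by one-letter code.
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Net charge at physiological pH: Lys/Arg +1, Asp/Glu -1, His partially
# protonated (+0.1), all others 0.
RESIDUE_CHARGE <- local({
  z <- setNames(numeric(20), AA_STANDARD20)
  z[c("K", "R")] <- 1
  z[c("D", "E")] <- -1
  z["H"] <- 0.1
  z
})

AROMATIC_RESIDUES <- c("F", "W", "Y", "H")

windowIds <- function(windows) {
  paste(windows$substrateId, windows$p1Position, sep = ":")
}

splitResidues <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map a seed plus a stream offset to a reproducible child seed < 2^31.
childSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) * 7919L
}
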