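# Shared fixtures and independent oracles used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomWindow <- function() paste(sample(AA20, 16, replace = TRUE),
                                 collapse = "")

# Write a tiny FASTA + annotation pair; returns the two paths.
writeToyData <- function(seqs, annotations) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("substrate_id\tp1_position",
               vapply(seq_len(nrow(annotations)), function(i)
                 paste(annotations$substrate_id[i],
                       annotations$p1_position[i], sep = "\t"),
                 character(1))), tsv)
  list(fasta = fa, tsv = tsv)
}

# Brute-force all-pairs AUC oracle (ties count 1/2).
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels != 1]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Trapezoidal AUC from an independently built empirical ROC curve.
trapezoidAUC <- function(scores, labels) {
  pts <- rocPoints(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# Independent greedy MID mRMR oracle: exhaustive objective recomputation at
# every step using the exported discretizer and pairwise MI only.
bruteMrmrTrace <- function(x, labels, m) {
  disc <- discretizeFeatures(x)
  rel <- vapply(seq_len(ncol(disc)), function(j)
    mutualInformation(disc[, j], labels), numeric(1))
  selected <- integer(0)
  trace <- character(0)
  for (step in seq_len(m)) {
    obj <- vapply(seq_len(ncol(disc)), function(j) {
      if (j %in% selected) return(-Inf)
      if (!length(selected)) return(rel[j])
      red <- mean(vapply(selected, function(s)
        mutualInformation(disc[, j], disc[, s]), numeric(1)))
      rel[j] - red
    }, numeric(1))
    pick <- which.max(obj)
    selected <- c(selected, pick)
    trace <- c(trace, colnames(x)[pick])
  }
  trace
}

# A labelled toy feature matrix with one informative column among noise.
plantedMatrix <- function(n = 60, p = 6, seed = 1, informativeShift = 2) {
  set.seed(seed)
  labels <- rep(c(1, -1), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1] <- x[, 1] + informativeShift * labels
  list(x = x, labels = labels)
}

# Two well-separated 2D Gaussian clouds (linearly separable for SVR tests).
separableData <- function(n = 40, seed = 1) {
  set.seed(seed)
  labels <- rep(c(1, -1), each = n / 2)
  x <- cbind(f1 = rnorm(n, mean = 3 * labels, sd = 0.3),
             f2 = rnorm(n, mean = -2 * labels, sd = 0.3))
  list(x = x, labels = labels)
}

smallGridConfig <- function(seed = 1L, folds = 5L)
  svrConfig(costGrid = c(1, 32), gammaGrid = c(0.001, 0.01),
            cvFolds = folds, seed = seed)
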