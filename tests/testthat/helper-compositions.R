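# Shared fixtures: random compositions and independent hand-coded index
# oracles (scalar arithmetic straight from the formulas, no package code).

PRIME <- "′"
ID_IIIa6 <- paste0("IIIa", PRIME)
ID_IIa6 <- paste0("IIa", PRIME)
ID_IIb6 <- paste0("IIb", PRIME)
ID_IIc6 <- paste0("IIc", PRIME)

# the 11 compounds routinely detected in deep-sea sediments
DETECTED11 <- c("Ia", "Ib", "Ic",
                "IIa", ID_IIa6, "IIb", ID_IIb6, "IIc", ID_IIc6,
                "IIIa", ID_IIIa6)

# n random compositions over the given ids; zero_prob introduces exact
# zeros to exercise undefined/flag paths
random_compositions <- function(n, ids = DETECTED11, zero_prob = 0) {
  g <- matrix(stats::rgamma(n * length(ids), shape = 0.8), nrow = n)
  if (zero_prob > 0) {
    g[matrix(stats::runif(n * length(ids)) < zero_prob, nrow = n)] <- 0
  }
  keep <- rowSums(g) > 0
  g <- g[keep, , drop = FALSE]
  g <- g / rowSums(g)
  colnames(g) <- ids
  as.data.frame(g, check.names = FALSE)
}

getc <- function(v, id) {
  x <- v[[id]]
  if (is.null(x) || is.na(x)) 0 else x
}

oracle_imbt <- function(v) {
  num <- getc(v, ID_IIIa6) + getc(v, ID_IIa6)
  den <- getc(v, "IIIa") + getc(v, ID_IIIa6) + getc(v, "IIa") +
    getc(v, ID_IIa6) + getc(v, "Ia")
  if (den == 0 || num == 0) return(NA_real_)
  -log10(num / den)
}

oracle_bit <- function(v) {
  num <- getc(v, "Ia") + getc(v, "IIa") + getc(v, "IIIa") +
    getc(v, ID_IIa6) + getc(v, ID_IIIa6)
  den <- num + getc(v, "Cren")
  if (den == 0) return(NA_real_)
  num / den
}

oracle_ir <- function(v) {
  num <- getc(v, ID_IIa6) + getc(v, ID_IIb6) + getc(v, ID_IIc6) +
    getc(v, ID_IIIa6) + getc(v, paste0("IIIb", PRIME)) +
    getc(v, paste0("IIIc", PRIME))
  den <- num + getc(v, "IIa") + getc(v, "IIb") + getc(v, "IIc") +
    getc(v, "IIIa") + getc(v, "IIIb") + getc(v, "IIIc")
  if (den == 0) return(NA_real_)
  num / den
}

oracle_mbt5me <- function(v) {
  num <- getc(v, "Ia") + getc(v, "Ib") + getc(v, "Ic")
  den <- num + getc(v, "IIa") + getc(v, "IIb") + getc(v, "IIc") +
    getc(v, "IIIa")
  if (den == 0) return(NA_real_)
  num / den
}

oracle_cbt5me <- function(v) {
  num <- getc(v, "Ib") + getc(v, "IIb")
  den <- getc(v, "Ia") + getc(v, "IIa")
  if (den == 0 || num == 0) return(NA_real_)
  -log10(num / den)
}

oracle_siiia_siia <- function(v) {
  num <- getc(v, "IIIa") + getc(v, ID_IIIa6)
  den <- getc(v, "IIa") + getc(v, ID_IIa6)
  if (den == 0) return(NA_real_)
  num / den
}

oracle_ternary <- function(v) {
  tetra <- getc(v, "Ia") + getc(v, "Ib") + getc(v, "Ic")
  penta <- getc(v, "IIa") + getc(v, ID_IIa6) + getc(v, "IIb") +
    getc(v, ID_IIb6) + getc(v, "IIc") + getc(v, ID_IIc6)
  hexa <- getc(v, "IIIa") + getc(v, ID_IIIa6) + getc(v, "IIIb") +
    getc(v, paste0("IIIb", PRIME)) + getc(v, "IIIc") +
    getc(v, paste0("IIIc", PRIME))
  tot <- tetra + penta + hexa
  c(tetra = tetra, penta = penta, hexa = hexa) / tot
}

# write a small peak-table CSV and return its path
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     fileEncoding = "UTF-8", qmethod = "double")
  path
}
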