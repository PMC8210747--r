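## shared fixture builders for the test suite; everything is generated in
## code under fixed seeds

CONS <- simulationConfig()@ancestralMonomer

## a one-species configuration with explicit array content
oneSpeciesConfig <- function(seed, nArrays, copies, bg = 30000L,
                             nPairs = 5000L, branchLength = 0,
                             substitutionRate = 0, errorRate = 0,
                             longRead = list()) {
    simulationConfig(
        seed = seed,
        species = data.frame(name = "sp", branchLength = branchLength),
        substitutionRate = substitutionRate,
        amplification = data.frame(name = "sp", nArrays = nArrays,
                                   minCopies = copies, maxCopies = copies),
        backgroundLength = bg,
        shortRead = list(nPairs = nPairs, errorRate = errorRate),
        longRead = longRead)
}

## random DNA of a given A+T fraction
randomDna <- function(n, at = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
          collapse = "")
}

## rotate a string left by k
rotate <- function(x, k) {
    n <- nchar(x)
    k <- k %% n
    if (k == 0) return(x)
    paste0(substring(x, k + 1, n), substring(x, 1, k))
}

## independent K2P evaluation used as the closed-form oracle: site classes
## counted with a lookup table, logs evaluated directly
k2pOracle <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    pur <- c("A", "G")
    d <- ca != cb
    ts <- sum(d & ((ca %in% pur) == (cb %in% pur)))
    tv <- sum(d) - ts
    L <- length(ca)
    P <- ts / L; Q <- tv / L
    -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}
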