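# Shared fixtures built in code.

# 6-node toy: two blocks of 3; binary edges (1,2),(1,3),(2,3),(4,5),(3,4)
toyBinaryGraph <- function() {
  a <- matrix(0, 6, 6)
  a[rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(3, 4))] <- 1
  fcprom:::FcGraph(a + t(a), "binary")
}

# weighted variant: 0.8 on the three block-1 edges, 0.6 on (4,5), 0.2 on (3,4)
toyWeightedFC <- function() {
  a <- matrix(0, 6, 6)
  a[rbind(c(1, 2), c(1, 3), c(2, 3))] <- 0.8
  a[4, 5] <- 0.6
  a[3, 4] <- 0.2
  ConnectomeMatrix(a + t(a), label = "toy")
}

toyPartition <- function() Partition(c(1, 1, 1, 2, 2, 2))

randomConnectome <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(stats::runif(n * n, -1, 1), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    ConnectomeMatrix(a)
  })
}

randomPartition <- function(n, k, seed) {
  withr::with_seed(seed, Partition(c(seq_len(k), sample.int(k, n - k, TRUE))))
}

# direct nonsymmetric eigensolve of PQ: independent route for the SNR
snrDirect <- function(params) {
  ev <- eigen(profileMatrix(params), only.values = TRUE)$values
  ev <- Re(ev[order(abs(ev), decreasing = TRUE)])
  if (abs(ev[1]) <= 1e-12) return(0)
  ev[2]^2 / ev[1]
}

writeTempMatrix <- function(m, sep = " ") {
  f <- tempfile(fileext = ".txt")
  utils::write.table(m, f, sep = sep, row.names = FALSE, col.names = FALSE)
  f
}

writeTempPartition <- function(labels) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(seq_along(labels), labels), f, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  f
}
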