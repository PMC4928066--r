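# Small in-code fixtures shared across test files.

tiny_otu <- function() {
  counts <- matrix(c(5L, 3L, 0L,
                     2L, 0L, 7L,
                     1L, 4L, 4L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"),
                                   c("otu1", "otu2", "otu3")))
  otu_table(counts, c(otu1 = "k__Bacteria; p__Acidobacteria; c__X",
                      otu2 = "k__Bacteria; p__Proteobacteria; c__Y",
                      otu3 = "unclassified"))
}

tiny_frame <- function(ids = c("A", "B", "C")) {
  n <- length(ids)
  tibble::tibble(sample_id = ids,
                 site_id = rep(c("s1", "s2"), length.out = n),
                 plot_id = paste0("p", seq_len(n)),
                 latitude = seq(25, 30, length.out = n),
                 longitude = seq(109, 111, length.out = n),
                 elevation = seq(500, 900, length.out = n))
}

# random labelled distance matrix from points in the plane
random_dist <- function(n, seed, kind = "scalar-difference") {
  withr::with_seed(seed, {
    pts <- matrix(stats::rnorm(n * 2), n)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    dist_matrix(d, kind)
  })
}

# Hand-worked array fixture: 2 sites x 10 samples, 30 probes.
# Probe values are the probe index (1..30) wherever detected.
#   p01 (FTHFS): detected in 5/10 site-A samples, 10/10 site-B -> the
#                filter masks it at A, keeps it at B.
#   p11 (ureC):  detected 10/10 at A, 2/10 at B -> kept at A, masked at B.
#   all other probes detected everywhere.
geochip_fixture <- function() {
  samples <- c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10))
  probes <- sprintf("p%02d", 1:30)
  category <- stats::setNames(rep(c("FTHFS", "ureC", "ppk"), each = 10),
                              probes)
  site_of <- stats::setNames(rep(c("siteA", "siteB"), each = 10), samples)
  m <- matrix(rep(1:30, each = 20), nrow = 20,
              dimnames = list(samples, probes))
  m[6:10, "p01"] <- NA          # p01 undetected in A06..A10 (5/10 at A)
  m[13:20, "p11"] <- NA         # p11 undetected in B03..B10 (2/10 at B)
  signal_table(m, category, site_of)
}
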