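test_that("seed correlations match the definitional covariance oracle", {
  set.seed(51)
  m <- matrix(rnorm(5 * 5), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  prof <- seed_correlations(m, "g1")
  oracle <- sapply(paste0("g", 2:5), function(g) {
    x <- m["g1", ]; y <- m[g, ]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  })
  expect_equal(prof$r[match(names(oracle), prof$gene)], unname(oracle),
               tolerance = 1e-12)
  expect_false("g1" %in% prof$gene)  # no self-correlation
})

test_that("seed correlations hit the exact bounds and drop flat genes", {
  m <- rbind(seed = 1:6, same = (1:6) * 3 + 2, anti = -(1:6) + 10,
             flat = rep(1, 6))
  colnames(m) <- paste0("s", 1:6)
  expect_warning(prof <- seed_correlations(m, "seed"), "zero-variance")
  expect_equal(prof$r[prof$gene == "same"], 1, tolerance = 1e-12)
  expect_equal(prof$r[prof$gene == "anti"], -1, tolerance = 1e-12)
  expect_false("flat" %in% prof$gene)
  expect_error(seed_correlations(m, "nope"), "not found")
  expect_error(seed_correlations(m[, 1:2], "seed"), ">= 3 subjects")
})

test_that("correlations are invariant to affine rescaling of a gene", {
  set.seed(52)
  m <- matrix(rnorm(4 * 20), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:20)))
  m2 <- m
  m2["g2", ] <- 5 * m2["g2", ] + 100
  p1 <- seed_correlations(m, "g1")
  p2 <- seed_correlations(m2, "g1")
  expect_equal(p1$r, p2$r, tolerance = 1e-12)
})

test_that("profile averaging gates on similarity and averages element-wise", {
  mk <- function(r, region) {
    out <- tibble::tibble(gene = c("a", "b"), r = r)
    attr(out, "seed_gene") <- "SST"
    attr(out, "region") <- region
    class(out) <- c("correlation_profile", class(out))
    out
  }
  avg <- average_profiles(mk(c(0.8, 0.2), "BA11"), mk(c(0.6, 0.0), "BA47"))
  expect_equal(avg$r, c(0.7, 0.1))
  expect_equal(attr(avg, "similarity"), 1)

  same <- average_profiles(mk(c(0.5, -0.2), "BA11"), mk(c(0.5, -0.2), "BA47"))
  expect_equal(same$r, c(0.5, -0.2))

  expect_error(
    average_profiles(mk(c(0.8, 0.2), "BA11"), mk(c(-0.8, -0.2), "BA47")),
    "similarity"
  )
})

test_that("select_top applies strict threshold, ordering and truncation", {
  prof <- tibble::tibble(gene = c("A", "B", "C"), r = c(0.9, 0.73, 0.7))
  expect_equal(select_top(prof)$gene, c("A", "B"))

  set.seed(53)
  big <- tibble::tibble(gene = sprintf("g%03d", 1:250),
                        r = runif(250, 0.73, 0.99))
  top <- select_top(big)
  oracle <- big[order(-big$r, big$gene), ]
  oracle <- oracle[oracle$r > 0.725, ][1:200, ]
  expect_equal(top$gene, oracle$gene)
  expect_equal(nrow(top), 200)

  # deterministic lexicographic tie-break
  tie <- tibble::tibble(gene = c("zzz", "aaa", "mmm"), r = c(0.8, 0.8, 0.8))
  expect_equal(select_top(tie, k = 2, r_min = 0)$gene, c("aaa", "mmm"))
})

test_that("build_network keeps strictly supra-threshold symmetric edges", {
  set.seed(54)
  n <- 30
  f <- rnorm(n)
  m <- rbind(
    a = 0.95 * f + 0.3 * rnorm(n),
    b = 0.95 * f + 0.3 * rnorm(n),
    c = 0.95 * f + 0.3 * rnorm(n),
    d = rnorm(n)
  )
  colnames(m) <- paste0("s", 1:n)
  net <- build_network(m, c("a", "b", "c", "d"), threshold = 0.5)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("a b", "a c", "b c"))
  # weights equal the correlation matrix entries
  cm <- cor(t(m))
  for (i in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$weight[i],
                 cm[net$edges$from[i], net$edges$to[i]], tolerance = 1e-12)
  }
  expect_warning(build_network(m, c("a", "b", "nope"), 0.5), "nope")
  expect_error(suppressWarnings(build_network(m, c("a", "nope"), 0.5)),
               "fewer than 2")
})

test_that("edge sets are monotone in the threshold", {
  set.seed(55)
  for (rep in 1:5) {
    m <- matrix(rnorm(8 * 40), nrow = 8,
                dimnames = list(paste0("g", 1:8), NULL))
    colnames(m) <- paste0("s", 1:40)
    lo <- build_network(m, rownames(m), threshold = 0.1)
    hi <- build_network(m, rownames(m), threshold = 0.3)
    expect_true(all(paste(hi$edges$from, hi$edges$to) %in%
                      paste(lo$edges$from, lo$edges$to)))
  }
})

test_that("core_module equals the brute-force common-neighbor oracle", {
  core_oracle <- function(nodes, edges, seeds, quota) {
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(edges))) {
      adj[edges$from[i], edges$to[i]] <- TRUE
      adj[edges$to[i], edges$from[i]] <- TRUE
    }
    counts <- sapply(nodes, function(v) sum(adj[v, seeds]))
    sort(union(seeds, nodes[counts >= quota]))
  }
  set.seed(56)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    nodes <- paste0("g", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.35
    edges <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                            weight = runif(sum(keep), 0.5, 1))
    net <- manual_network(nodes, edges)
    seeds <- sample(nodes, 3)
    quota <- 2
    got <- suppressWarnings(core_module(net, seeds, quota = quota))
    expect_equal(as.character(got), core_oracle(nodes, edges, seeds, quota))
  }
})

test_that("core_module handles stars, seed-only graphs and disconnection", {
  seeds_only <- manual_network(
    c("s1", "s2", "s3"),
    tibble::tibble(from = c("s1", "s1", "s2"), to = c("s2", "s3", "s3"),
                   weight = rep(0.8, 3))
  )
  expect_equal(as.character(core_module(seeds_only, c("s1", "s2", "s3"))),
               c("s1", "s2", "s3"))

  star <- manual_network(
    c("s1", "s2", "s3", "n1", "n2", "n3"),
    tibble::tibble(
      from = c("s1", "s1", "s2",
               rep(c("n1", "n2", "n3"), each = 3)),
      to = c("s2", "s3", "s3", rep(c("s1", "s2", "s3"), 3)),
      weight = rep(0.9, 12)
    )
  )
  expect_equal(as.character(core_module(star, c("s1", "s2", "s3"))),
               c("n1", "n2", "n3", "s1", "s2", "s3"))

  split_net <- manual_network(
    c("s1", "s2", "x"),
    tibble::tibble(from = "s1", to = "x", weight = 0.7)
  )
  expect_warning(got <- core_module(split_net, c("s1", "s2")),
                 "different components")
  expect_true(attr(got, "disconnected"))
  expect_error(core_module(split_net, c("s1", "nope")), "not in network")
})
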