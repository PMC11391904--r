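test_that("neighbor lists contain exactly the in-range ordered pairs", {
  g2 <- geometry(c(1, 1), rbind(c(0, 0, 0), c(1, 0, 0)))
  nb <- build_neighborhood(g2, 2)
  expect_equal(nrow(nb), 2)
  expect_equal(sort(nb$d), c(1, 1))
  expect_equal(nrow(build_neighborhood(g2, 0.5)), 0)
  ## 4-atom square, cutoff just above the edge: 8 ordered edge pairs,
  ## diagonals excluded; verified against a brute-force enumeration
  d <- 1.7
  gsq <- geometry(rep(6, 4), rbind(c(0, 0, 0), c(d, 0, 0),
                                   c(d, d, 0), c(0, d, 0)))
  nb <- build_neighborhood(gsq, d * 1.01)
  expect_equal(nrow(nb), 8)
  brute <- subset(expand.grid(i = 1:4, j = 1:4), i != j)
  bd <- sqrt(rowSums((gsq$positions[brute$j, ] -
                        gsq$positions[brute$i, ])^2))
  keep <- brute[bd <= d * 1.01, ]
  expect_setequal(paste(nb$i, nb$j), paste(keep$i, keep$j))
  ## displacement consistency
  for (r in seq_len(nrow(nb))) {
    expect_equal(unlist(nb[r, c("dx", "dy", "dz")], use.names = FALSE),
                 gsq$positions[nb$j[r], ] - gsq$positions[nb$i[r], ])
  }
})

test_that("radial basis is enveloped to zero at the cutoff", {
  cfg <- rep_config("invariant", cutoff = 5, n_radial_basis = 10)
  expect_equal(radial_basis(5, cfg), matrix(0, 1, 10))
  expect_equal(radial_basis(7, cfg), matrix(0, 1, 10))
  ## cosine envelope value at half the cutoff is exactly 1/2
  mid <- radial_basis(2.5, cfg)
  raw <- exp(-(2.5 - seq(0, 5, length.out = 10))^2 /
               (2 * (5 / 9)^2))
  expect_equal(as.numeric(mid), raw * 0.5, tolerance = 1e-12)
  set.seed(8)
  r <- runif(1000, 0.05, 8)
  vals <- radial_basis(r, cfg)
  expect_true(all(is.finite(vals)) && all(vals >= 0) && all(vals <= 1))
})

test_that("scalar features are invariant and vector features equivariant", {
  set.seed(9)
  for (kind in c("invariant", "equivariant")) {
    cfg <- rep_config(kind, n_features = 8, n_interactions = 2,
                      cutoff = 10, n_radial_basis = 6, seed = 3)
    g <- random_geom(5)
    enc <- encode(g, cfg)
    for (rep in 1:50) {
      R <- rand_rotation()
      tr <- rnorm(3)
      g2 <- geometry(g$atomic_numbers,
                     g$positions %*% t(R) + rep(tr, each = 5))
      enc2 <- encode(g2, cfg)
      expect_equal(enc2$scalars, enc$scalars, tolerance = 1e-6)
      if (kind == "equivariant") {
        rot <- array(0, dim(enc$vectors))
        for (a in 1:3) {
          for (b in 1:3) rot[, , a] <- rot[, , a] + R[a, b] * enc$vectors[, , b]
        }
        expect_equal(enc2$vectors, rot, tolerance = 1e-5)
      }
    }
  }
})

test_that("swapping identical atoms permutes the feature rows", {
  cfg <- rep_config("equivariant", n_features = 8, n_interactions = 1,
                    n_radial_basis = 6, seed = 3)
  pos <- rbind(c(0, 0, 0), c(1.8, 0, 0), c(0, 1.6, 0.3), c(-1, -1, 0.5))
  g <- geometry(c(6, 1, 1, 8), pos)
  gswap <- geometry(c(6, 1, 1, 8), pos[c(1, 3, 2, 4), ])
  e1 <- encode(g, cfg)
  e2 <- encode(gswap, cfg)
  expect_equal(e2$scalars, e1$scalars[c(1, 3, 2, 4), ], tolerance = 1e-12)
  expect_equal(e2$vectors, e1$vectors[c(1, 3, 2, 4), , ], tolerance = 1e-12)
})

test_that("features are local: atoms beyond the receptive field cannot matter", {
  cfg <- rep_config("equivariant", n_features = 8, n_interactions = 1,
                    cutoff = 3, n_radial_basis = 6, seed = 3)
  near <- rbind(c(0, 0, 0), c(2, 0, 0))
  far0 <- c(20, 0, 0)
  g1 <- geometry(c(6, 1, 8), rbind(near, far0))
  g2 <- geometry(c(6, 1, 8), rbind(near, far0 + c(0.7, -0.3, 0.2)))
  e1 <- encode(g1, cfg)
  e2 <- encode(g2, cfg)
  expect_identical(e1$scalars[1:2, ], e2$scalars[1:2, ])
})

test_that("feature gradients with respect to positions match finite differences", {
  cfg <- rep_config("equivariant", n_features = 6, n_interactions = 1,
                    n_radial_basis = 6, seed = 4)
  set.seed(10)
  g <- random_geom(3)
  params <- getFromNamespace("with_preserved_seed", "namdnet")(
    cfg$seed, getFromNamespace("init_representation_params", "namdnet")(cfg))
  fsum <- function(pos, want_grad = FALSE) {
    batch <- getFromNamespace("make_batch", "namdnet")(
      list(geometry(g$atomic_numbers, pos)), cfg$cutoff)
    pn <- getFromNamespace("ag_leaf", "namdnet")(batch$pos, track = TRUE)
    P <- lapply(params, getFromNamespace("ag_const", "namdnet"))
    out <- getFromNamespace("rep_forward", "namdnet")(cfg, P, batch, pn)
    f <- getFromNamespace("ag_sum_all", "namdnet")(
      getFromNamespace("ag_square", "namdnet")(out$s))
    if (want_grad) {
      getFromNamespace("ag_grad", "namdnet")(f, pn)[[1]]$value
    } else f$value[1]
  }
  gan <- fsum(g$positions, want_grad = TRUE)
  h <- 1e-4
  for (a in 1:3) {
    for (x in 1:3) {
      pp <- g$positions; pp[a, x] <- pp[a, x] + h
      pm <- g$positions; pm[a, x] <- pm[a, x] - h
      fd <- (fsum(pp) - fsum(pm)) / (2 * h)
      expect_equal(gan[a, x], fd, tolerance = 1e-5)
    }
  }
})
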