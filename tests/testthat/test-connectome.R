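test_that("constructor validates shape, sign, diagonal and labels", {
  w <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_s3_class(connectome(w, c("a", "b")), "connectome")
  expect_error(connectome(matrix(0, 2, 3)), "square")
  wneg <- w; wneg[2, 1] <- -0.1
  expect_error(connectome(wneg, c("a", "b")), "negative weight")
  wdiag <- w; diag(wdiag) <- c(0, 1)
  expect_error(connectome(wdiag, c("a", "b")), "diagonal")
  expect_error(connectome(w, c("a", "a")), "unique")
  expect_error(connectome(w, c("a", "b", "c")), "labels")
})

test_that("CSV round-trip restores weights to full precision", {
  conn <- generate_synthetic_connectome(7, density = 0.5, seed = 3)
  path <- file.path(tempdir(), "conn.csv")
  write_connectome(conn, path)
  back <- load_connectome(path)
  expect_identical(back$weights, conn$weights)
  expect_identical(back$labels, conn$labels)
  expect_identical(back$stroke_region, conn$stroke_region)
  expect_identical(back$hemisphere, conn$hemisphere)
  file.remove(path, paste0(sub("\\.csv$", "", path), ".meta.json"))
})

test_that("loader rejects malformed files", {
  p <- file.path(tempdir(), "bad1.csv")
  writeLines(c("a,b", "0,1", "x,0"), p)
  expect_error(load_connectome(p), "non-numeric")
  writeLines(c("a,b,c", "0,1,2", "3,0,4"), p)
  expect_error(load_connectome(p), "square")
  writeLines(c("a,b", "0,-0.1", "1,0"), p)
  expect_error(load_connectome(p), "negative")
  file.remove(p)
  expect_error(load_connectome(p), "no such file")
})

test_that("synthetic generator is seed-deterministic and honours its knobs", {
  a <- generate_synthetic_connectome(18, density = 0.3, seed = 1)
  b <- generate_synthetic_connectome(18, density = 0.3, seed = 1)
  expect_identical(a$weights, b$weights)
  expect_false(identical(
    a$weights, generate_synthetic_connectome(18, density = 0.3, seed = 2)$weights))

  sym <- generate_synthetic_connectome(12, density = 0.4, symmetric = TRUE,
                                       seed = 5)
  expect_equal(sym$weights, t(sym$weights))

  full <- generate_synthetic_connectome(12, density = 1, seed = 2)
  off <- full$weights[row(full$weights) != col(full$weights)]
  expect_true(all(off > 0))

  expect_error(generate_synthetic_connectome(2), "at least 3")
  expect_error(generate_synthetic_connectome(10, density = 0), "density")
  expect_identical(a$labels[a$stroke_region], "rM1")
})

test_that("apply_stroke scales exactly the stroke region's links", {
  conn <- toy_conn3()
  same <- apply_stroke(conn, lesion_spec(retain = 1))
  expect_identical(same$weights, conn$weights)

  gone <- apply_stroke(conn, lesion_spec(retain = 0))
  expect_true(all(gone$weights[1, ] == 0) && all(gone$weights[, 1] == 0))
  expect_identical(gone$weights[2:3, 2:3], conn$weights[2:3, 2:3])

  half <- apply_stroke(conn, lesion_spec(retain = 0.5))
  expect_equal(half$weights[2, 1], 2)
  expect_equal(half$weights[3, 2], conn$weights[3, 2])

  # input untouched
  expect_equal(conn$weights[2, 1], 4)
  expect_error(apply_stroke(conn, lesion_spec(stroke_region = 9, retain = 0.5)),
               "out of range")
})

test_that("stroke damage composes multiplicatively and is directional on request", {
  conn <- generate_synthetic_connectome(10, seed = 8)
  s1 <- 0.7; s2 <- 0.4
  twice <- apply_stroke(apply_stroke(conn, lesion_spec(retain = s1)),
                        lesion_spec(retain = s2))
  once <- apply_stroke(conn, lesion_spec(retain = s1 * s2))
  expect_equal(twice$weights, once$weights, tolerance = 1e-15)

  aff <- apply_stroke(conn, lesion_spec(retain = 0), direction = "afferent")
  k <- conn$stroke_region
  expect_true(all(aff$weights[k, ] == 0))
  expect_identical(aff$weights[-k, ], conn$weights[-k, ])
})

test_that("rebound conserves the redistribution budget on random connectomes", {
  for (n in c(5, 12, 27, 50)) {
    conn <- generate_synthetic_connectome(n, density = 0.4, seed = n)
    for (case in list(c(0.0, 0.5), c(0.3, 1.0), c(0.7, 5.0), c(0.9, 2.5))) {
      spec <- lesion_spec(retain = case[1], rebound = case[2])
      les <- apply_stroke(conn, spec)
      reb <- apply_rebound(conn, spec)
      lost <- sum(conn$weights) - sum(les$weights)
      added <- sum(reb$weights) - sum(les$weights)
      expect_equal(added, case[2] * lost, tolerance = 1e-9)
      expect_true(all(reb$weights >= 0))
      expect_true(all(diag(reb$weights) == 0))
      # stroke row/column untouched by redistribution
      k <- conn$stroke_region
      expect_equal(reb$weights[k, ], les$weights[k, ])
      expect_equal(reb$weights[, k], les$weights[, k])
    }
  }
})

test_that("rebound with r = 0 equals the plain lesion; s = 1, r = 0 is the identity", {
  conn <- generate_synthetic_connectome(9, seed = 4)
  spec <- lesion_spec(retain = 0.5, rebound = 0)
  expect_identical(apply_rebound(conn, spec)$weights,
                   apply_stroke(conn, spec)$weights)
  id <- apply_rebound(conn, lesion_spec(retain = 1, rebound = 0))
  expect_identical(id$weights, conn$weights)
})

test_that("single-donor rebound matches the hand-worked factor", {
  conn <- toy_conn4_single_donor()
  spec <- lesion_spec(retain = 0, rebound = 1)
  reb <- apply_rebound(conn, spec)
  # lost = w[2,1] + w[1,2] = 5; budget = 5; donor 2's other links sum to
  # 1 + 0.5 + 2 + 1.5 = 5, so every such link scales by 1 + 5/5 = 2
  expect_equal(reb$weights[3, 2], 2 * 1)
  expect_equal(reb$weights[2, 3], 2 * 0.5)
  expect_equal(reb$weights[4, 2], 2 * 2)
  expect_equal(reb$weights[2, 4], 2 * 1.5)
  # the non-donor link is untouched
  expect_equal(reb$weights[4, 3], 0.25)

  # restore mode rebuilds the stroke links instead
  res <- apply_rebound(conn, spec, mode = "restore")
  expect_equal(res$weights[2, 1], 3)
  expect_equal(res$weights[1, 2], 2)
})

test_that("rebound errors when nothing was connected to the stroke region", {
  w <- matrix(0, 4, 4)
  w[3, 2] <- 1; w[2, 3] <- 2; w[4, 3] <- 1
  conn <- connectome(w, stroke_region = 1L)
  expect_error(apply_rebound(conn, lesion_spec(retain = 0, rebound = 1)),
               "no node was connected")
})

test_that("lesion_spec validates parameter ranges", {
  expect_error(lesion_spec(retain = -0.1), "retain")
  expect_error(lesion_spec(retain = 1.1), "retain")
  expect_error(lesion_spec(rebound = 5.5), "rebound")
})
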