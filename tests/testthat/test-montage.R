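test_that("SFP files round-trip and parse as written", {
  m <- toy_montage(8)
  path <- withr::local_tempfile(fileext = ".sfp")
  save_montage(m, path)
  m2 <- load_montage(path)
  expect_identical(m2$labels, m$labels)
  expect_lt(max(abs(m2$positions - m$positions)), 1e-9)

  # hand-written file parses to exactly the written records, in order
  p2 <- withr::local_tempfile(fileext = ".sfp")
  writeLines(c("# comment", "Oz 0 -100 0", "Cz 0 0 100", "Fz 0 80 60"), p2)
  m3 <- load_montage(p2)
  expect_identical(m3$labels, c("Oz", "Cz", "Fz"))
  expect_equal(unname(m3$positions[1, ]), c(0, -100, 0))
  expect_identical(m3$reference, "average")
})

test_that("malformed montage files fail loudly", {
  p <- withr::local_tempfile(fileext = ".sfp")
  writeLines(c("Oz 0 -100 0", "Oz 1 2 3"), p)
  expect_error(load_montage(p), "duplicate")
  writeLines(c("Oz 0 -100 zzz"), p)
  expect_error(load_montage(p), "non-numeric")
})

test_that("the master montage is dense, unique and anchor-complete", {
  m <- master_montage()
  expect_gte(n_electrodes(m), 256)
  expect_identical(anyDuplicated(m$labels), 0L)
  expect_true(all(alignment_anchors() %in% m$labels))
  # all electrodes on the scalp sphere
  expect_equal(unname(sqrt(rowSums(m$positions^2))),
               rep(92, n_electrodes(m)), tolerance = 1e-9)
})

test_that("montage subsets are nested and sized as requested", {
  subs <- montage_subsets(master_montage(), c(32, 64, 128, 256))
  expect_identical(unname(vapply(subs, n_electrodes, 1L)),
                   c(32L, 64L, 128L, 256L))
  expect_true(all(subs[["32"]]$labels %in% subs[["64"]]$labels))
  expect_true(all(subs[["64"]]$labels %in% subs[["128"]]$labels))
  expect_true(all(subs[["128"]]$labels %in% subs[["256"]]$labels))
})

test_that("the default anchor set is the 19 classic 10-20 electrodes", {
  expect_identical(
    alignment_anchors(),
    c("Fp1", "Fp2", "Fz", "F7", "F3", "C3", "T7", "P3", "P7", "Pz",
      "O1", "Oz", "O2", "P4", "P8", "T8", "C4", "F4", "F8")
  )
})

test_that("aligning a montage to itself gives the identity", {
  m <- master_montage()
  al <- affine_align(m, m)
  expect_equal(al$affine, cbind(diag(3), 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(al$rms_residual, 1e-9)
})

test_that("affine alignment recovers a known random transform", {
  m <- master_montage()
  set.seed(31)
  for (rep in 1:20) {
    # random rotation x anisotropic scale + translation
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    A <- R %*% diag(runif(3, 0.8, 1.2))
    t0 <- rnorm(3, 0, 20)
    warped <- montage(m$labels, m$positions %*% t(A) +
                        matrix(t0, n_electrodes(m), 3, byrow = TRUE))
    al <- affine_align(warped, m)
    # recovered map must be the inverse of the applied one
    expect_lt(max(abs(al$affine[, 1:3] %*% A - diag(3))), 1e-6)
    expect_lt(al$rms_residual, 1e-6)
    back <- affine_apply(al, warped$positions)
    expect_lt(max(abs(back - m$positions)), 1e-5)
  }
})

test_that("alignment rejects missing anchors and degenerate sets", {
  m <- master_montage()
  m2 <- toy_montage(8)
  expect_error(affine_align(m2, m), "missing")
  flat <- montage(c("a", "b", "c", "d", "e"),
                  cbind(seq_len(5), seq_len(5) * 2, 0))
  expect_error(affine_align(flat, flat, anchors = flat$labels), "coplanar|rank")
})

test_that("average referencing removes common mode and is idempotent", {
  set.seed(5)
  X <- matrix(rnorm(20), 5, 4)
  R1 <- apply_reference(X)
  expect_lt(max(abs(colMeans(R1))), 1e-12)
  expect_equal(apply_reference(R1), R1, tolerance = 1e-12)
  # constant columns vanish entirely
  C <- matrix(3.7, 5, 2)
  expect_equal(apply_reference(C), C * 0)
  # a label reference zeroes that row and is idempotent
  rownames(X) <- paste0("E", 1:5)
  R2 <- apply_reference(X, "E3")
  expect_equal(unname(R2["E3", ]), rep(0, 4))
  expect_equal(apply_reference(R2, "E3"), R2)
  expect_error(apply_reference(X, "E99"), "not found")
})

test_that("reference projectors are projectors with zero row sums", {
  for (ref in list("average", "E2")) {
    P <- reference_projector(6, ref, labels = paste0("E", 1:6))
    expect_equal(P %*% P, P, tolerance = 1e-12)
  }
  P <- reference_projector(6)
  expect_equal(rowSums(P), rep(0, 6), tolerance = 1e-12)
})

test_that("customize_templates subsets, reorders and re-references", {
  ts <- test_templates()
  mon <- ts$montage

  # full set: identity up to re-referencing
  out <- customize_templates(ts, mon)
  expect_equal(out$matrix, apply_reference(ts$matrix), tolerance = 1e-12,
               ignore_attr = TRUE)

  # 3-electrode subset under average reference: columns sum to zero over
  # the 3 retained rows
  tgt <- montage(mon$labels[c(5, 1, 9)], mon$positions[c(5, 1, 9), ])
  sub <- customize_templates(ts, tgt)
  expect_identical(rownames(sub$matrix), mon$labels[c(5, 1, 9)])
  expect_lt(max(abs(colSums(sub$matrix))), 1e-12)

  # permuting the target electrodes permutes the rows identically
  perm <- c(2, 3, 1)
  tgt_p <- montage(tgt$labels[perm], tgt$positions[perm, ])
  sub_p <- customize_templates(ts, tgt_p)
  expect_equal(sub_p$matrix, sub$matrix[perm, ], tolerance = 1e-12)

  expect_error(customize_templates(ts, toy_montage(4)), "not present")
})

test_that("nearest-position matching agrees with label matching under jitter", {
  ts <- test_templates()
  mon <- ts$montage
  keep <- c(2, 7, 11, 20, 25, 31)
  set.seed(99)
  jitter <- matrix(rnorm(length(keep) * 3), ncol = 3)
  jitter <- jitter / sqrt(rowSums(jitter^2)) # 1 mm displacement
  tgt <- montage(mon$labels[keep], mon$positions[keep, ] + jitter)
  by_lab <- customize_templates(ts, tgt, match_mode = "by_label")
  by_pos <- customize_templates(ts, tgt, match_mode = "nearest_position")
  expect_identical(by_pos$provenance$matched_from, mon$labels[keep])
  expect_equal(by_pos$matrix, by_lab$matrix, tolerance = 1e-12)
})

test_that("packaged montage fixtures match the generating code", {
  sfp <- system.file("extdata", "master_montage.sfp",
                     package = "eegtemplates")
  m_file <- load_montage(sfp)
  m_code <- master_montage()
  expect_identical(m_file$labels, m_code$labels)
  expect_lt(max(abs(m_file$positions - m_code$positions)), 1e-9)

  csv <- system.file("extdata", "montage_subsets.csv",
                     package = "eegtemplates")
  tab <- utils::read.csv(csv)
  subs <- montage_subsets(m_code)
  for (s in c(32, 64, 128, 256)) {
    expect_identical(tab$label[tab[[paste0("in", s)]]],
                     subs[[as.character(s)]]$labels)
  }
})
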