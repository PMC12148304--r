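gpo <- function(n) paste(rep("GPO", n), collapse = "")

test_that("Gly-X-Y validation scores compliance and locates violations", {
  r <- validate_gxy(gpo(10))
  expect_equal(r$compliance, 1)
  expect_true(is.na(r$first_violation))
  s <- gpo(10)
  substr(s, 13, 13) <- "A"  # Gly of triplet 5
  r2 <- validate_gxy(s)
  expect_equal(r2$compliance, 0.9)
  expect_equal(r2$first_violation, 5L)
  expect_error(validate_gxy("GP"), "triplet")
})

test_that("identity and point-substitution alignments behave analytically", {
  tpl <- triple_helix_sequence(rep(gpo(10), 3))
  ali <- align_to_template(tpl, rep(gpo(10), 3))
  expect_equal(ali$overall_identity, 100)
  expect_true(all(vapply(ali$chains, function(a) !any(a$state %in%
    c("insertion", "deletion")), logical(1))))
  # ungapping recovers the inputs
  a1 <- ali$chains[[1]]
  expect_equal(paste(a1$template[a1$template != "-"], collapse = ""), gpo(10))
  expect_equal(paste(a1$target[a1$target != "-"], collapse = ""), gpo(10))
  tgt <- rep(gpo(10), 3)
  substr(tgt[1], 5, 5) <- "A"
  ali2 <- align_to_template(tpl, tgt)
  expect_equal(unname(ali2$identity[1]), (30 - 1) / 30 * 100)
  expect_equal(sum(ali2$chains[[1]]$state == "mismatch"), 1)
})

test_that("a helical-region triplet deletion yields one frame-preserving gap", {
  # varied X/Y content so the deleted triplet is unambiguous
  tseq <- "GAOGPSGLOGMOGKOGHOGVO"
  tpl <- triple_helix_sequence(rep(tseq, 3))
  tgt <- rep(paste0(substr(tseq, 1, 9), substr(tseq, 13, nchar(tseq))), 3)
  ali <- align_to_template(tpl, tgt)
  a <- ali$chains[[1]]
  gaps <- which(a$target == "-")
  expect_length(gaps, 3)
  expect_equal(diff(gaps), c(1, 1))
  expect_equal(gaps, 10:12)
  expect_equal((gaps[1] - 1) %% 3, 0)  # gap starts on a triplet boundary
  # threaded result keeps a perfect Gly frame
  h <- make_triple_helix(n_res = nchar(tseq))
  thr <- thread_sequence(h, ali)
  seqs <- vapply(split(thr, thr$chain), function(cc) {
    paste(fibrilforge:::aa_to1(cc$resname[cc$atom == "CA"][order(cc$resid[cc$atom == "CA"])]),
          collapse = "")
  }, character(1))
  expect_equal(validate_gxy(seqs[[1]])$compliance, 1)
})

test_that("low-identity targets trigger the distant-homolog warning", {
  tpl <- triple_helix_sequence(rep(gpo(5), 3))
  expect_warning(align_to_template(tpl, rep("WWWWWWWWWWWWWWW", 3)),
                 "distant homolog")
})

test_that("threading preserves the backbone exactly", {
  tpl <- triple_helix_sequence(rep(gpo(10), 3))
  h <- make_triple_helix(n_res = 30)
  ali <- align_to_template(tpl, rep(gpo(10), 3))
  thr <- thread_sequence(h, ali)
  expect_equal(as.matrix(thr[, c("x", "y", "z")]),
               as.matrix(h[, c("x", "y", "z")]))
  # idempotent on identity alignments
  thr2 <- thread_sequence(thr, ali)
  expect_equal(thr2$resname, thr$resname)
  expect_equal(as.matrix(thr2[, c("x", "y", "z")]),
               as.matrix(thr[, c("x", "y", "z")]))
  # single substitution: backbone untouched everywhere, side chain swapped
  tgt <- rep(gpo(10), 3)
  substr(tgt[2], 6, 6) <- "V"  # an O -> V in chain B
  thr3 <- thread_sequence(h, align_to_template(tpl, tgt))
  bb <- c("N", "CA", "C", "O")
  expect_equal(as.matrix(thr3[thr3$atom %in% bb, c("x", "y", "z")]),
               as.matrix(h[h$atom %in% bb, c("x", "y", "z")]))
  res <- thr3[thr3$chain == "B" & thr3$resid == 6, ]
  expect_equal(res$resname[1], "VAL")
  expect_setequal(res$atom, c("N", "CA", "C", "O", "CB", "CG1", "CG2"))
  # per-residue all-atom displacement stays within the 2 A acceptance bound
  for (rid in unique(thr3$resid[thr3$chain == "B"])) {
    old <- h[h$chain == "B" & h$resid == rid, ]
    new <- thr3[thr3$chain == "B" & thr3$resid == rid, ]
    shared <- intersect(old$atom, new$atom)
    d <- sqrt(rowSums((as.matrix(new[match(shared, new$atom), c("x", "y", "z")]) -
                         as.matrix(old[match(shared, old$atom), c("x", "y", "z")]))^2))
    expect_lt(sqrt(mean(d^2)), 2)
  }
})

test_that("insertions inside the helical region are rejected", {
  tseq <- "GAOGPSGLOGMO"
  tpl <- triple_helix_sequence(rep(tseq, 3))
  h <- make_triple_helix(n_res = nchar(tseq))
  # hand-build an alignment with a helical insertion
  ali <- align_to_template(tpl, rep(tseq, 3))
  bad <- ali
  ins <- tibble::tibble(template = "-", target = "A", helical = FALSE,
                        state = "insertion")
  bad$chains[[1]] <- dplyr::bind_rows(bad$chains[[1]][1:6, ], ins,
                                      bad$chains[[1]][7:12, ])
  expect_error(thread_sequence(h, bad), "unsupported indel")
})

test_that("axial rise reports the construction parameter and scales linearly", {
  h <- make_triple_helix(n_res = 30, rise = 2.86)
  expect_equal(as.numeric(axial_rise(h)), 3 * 2.86, tolerance = 0.02)
  h2 <- h
  h2$z <- h2$z * 2
  expect_equal(as.numeric(axial_rise(h2)), 2 * as.numeric(axial_rise(h)),
               tolerance = 1e-6)
  h3 <- make_triple_helix(n_res = 30, rise = 3.1)
  expect_equal(as.numeric(axial_rise(h3)), 9.3, tolerance = 0.02)
  expect_error(axial_rise(h[h$resid < 4, ]), "glycine|triplets")
})
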