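test_that("canonical event fixtures classify exactly", {
  # cassette exon
  a <- tx_struct("a", "+", c(0, 100), c(200, 300), c(400, 500))
  b <- tx_struct("b", "+", c(0, 100), c(400, 500))
  expect_identical(classify_events(a, b), "exon_skipping")

  # intron retention
  a2 <- tx_struct("a", "+", c(0, 100), c(200, 300))
  b2 <- tx_struct("b", "+", c(0, 300))
  expect_identical(classify_events(a2, b2), "intron_retention")

  # tandem 5' UTR: same first-exon body, different start
  a3 <- tx_struct("a", "+", c(0, 100), c(200, 300))
  b3 <- tx_struct("b", "+", c(50, 100), c(200, 300))
  expect_identical(classify_events(a3, b3), "tandem_5utr")

  # tandem 3' UTR mirrored at the right terminus
  a3r <- tx_struct("a", "+", c(0, 100), c(200, 300))
  b3r <- tx_struct("b", "+", c(0, 100), c(200, 350))
  expect_identical(classify_events(a3r, b3r), "tandem_3utr")

  # alternative donor (5' splice site on + strand)
  a4 <- tx_struct("a", "+", c(0, 100), c(200, 300))
  b4 <- tx_struct("b", "+", c(0, 120), c(200, 300))
  expect_identical(classify_events(a4, b4), "alt_5ss")

  # alternative acceptor (3' splice site on + strand)
  a5 <- tx_struct("a", "+", c(0, 100), c(200, 300))
  b5 <- tx_struct("b", "+", c(0, 100), c(220, 300))
  expect_identical(classify_events(a5, b5), "alt_3ss")

  # mutually exclusive exons
  a6 <- tx_struct("a", "+", c(0, 100), c(200, 300), c(600, 700))
  b6 <- tx_struct("b", "+", c(0, 100), c(400, 500), c(600, 700))
  expect_identical(classify_events(a6, b6), "mutually_exclusive_exons")

  # alternative first exon carries the UTR label too
  a7 <- tx_struct("a", "+", c(0, 100), c(300, 400))
  b7 <- tx_struct("b", "+", c(120, 200), c(300, 400))
  expect_setequal(classify_events(a7, b7), c("alt_first_exon", "alt_5utr"))

  # alternative last exon
  a8 <- tx_struct("a", "+", c(0, 100), c(300, 400))
  b8 <- tx_struct("b", "+", c(0, 100), c(500, 600))
  expect_setequal(classify_events(a8, b8), c("alt_last_exon", "alt_3utr"))

  # overlapping isoform-specific internal exons fall back to complex
  a9 <- tx_struct("a", "+", c(0, 100), c(200, 300), c(600, 700))
  b9 <- tx_struct("b", "+", c(0, 100), c(250, 400), c(600, 700))
  expect_identical(classify_events(a9, b9), "complex_internal")
})

test_that("classification is empty iff structures are identical and symmetric", {
  a <- tx_struct("a", "+", c(0, 100), c(200, 300), c(400, 500))
  expect_identical(classify_events(a, a), character(0))

  b <- tx_struct("b", "+", c(0, 100), c(400, 500))
  expect_identical(sort(classify_events(a, b)), sort(classify_events(b, a)))

  a2 <- tx_struct("a", "+", c(0, 100), c(200, 300))
  b2 <- tx_struct("b", "-", c(0, 100), c(200, 300))
  expect_error(classify_events(a2, b2), "strand")
})

test_that("strand reversal maps 5' and 3' labels onto each other", {
  flip <- c(alt_5ss = "alt_3ss", alt_3ss = "alt_5ss",
            alt_first_exon = "alt_last_exon", alt_last_exon = "alt_first_exon",
            alt_5utr = "alt_3utr", alt_3utr = "alt_5utr",
            tandem_5utr = "tandem_3utr", tandem_3utr = "tandem_5utr",
            complex_5p = "complex_3p", complex_3p = "complex_5p",
            exon_skipping = "exon_skipping",
            intron_retention = "intron_retention",
            mutually_exclusive_exons = "mutually_exclusive_exons",
            complex_internal = "complex_internal")
  cases <- list(
    list(rbind(c(0, 100), c(200, 300)), rbind(c(0, 120), c(200, 300))),
    list(rbind(c(0, 100), c(200, 300)), rbind(c(50, 100), c(200, 300))),
    list(rbind(c(0, 100), c(300, 400)), rbind(c(120, 200), c(300, 400))),
    list(rbind(c(0, 100), c(200, 300), c(400, 500)), rbind(c(0, 100), c(400, 500))),
    list(rbind(c(0, 100), c(200, 300)), rbind(c(0, 300)))
  )
  for (cs in cases) {
    plus <- classify_events(transcript_structure("a", "+", cs[[1]]),
                            transcript_structure("b", "+", cs[[2]]))
    minus <- classify_events(transcript_structure("a", "-", cs[[1]]),
                             transcript_structure("b", "-", cs[[2]]))
    expect_setequal(minus, unname(flip[plus]))
  }
})

test_that("every differing structure yields at least one label", {
  set.seed(51)
  base <- rbind(c(0, 100), c(200, 300), c(400, 500), c(600, 700))
  for (i in 1:40) {
    ex <- base
    op <- sample(c("drop", "shift_start", "shift_end", "merge"), 1)
    if (op == "drop") {
      ex <- ex[-sample(2:3, 1), , drop = FALSE]
    } else if (op == "shift_start") {
      j <- sample(1:4, 1)
      ex[j, 1] <- ex[j, 1] + sample(c(-40, 40), 1)
    } else if (op == "shift_end") {
      j <- sample(1:4, 1)
      ex[j, 2] <- ex[j, 2] + sample(c(-40, 40), 1)
    } else {
      ex <- rbind(ex[1, , drop = FALSE], c(ex[2, 1], ex[3, 2]),
                  ex[4, , drop = FALSE])
    }
    ex <- ex[ex[, 2] > ex[, 1], , drop = FALSE]
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) next
    a <- transcript_structure("a", "+", base)
    b <- transcript_structure("b", "+", ex)
    if (identical(dim(a$exons), dim(b$exons)) && all(a$exons == b$exons)) next
    expect_gt(length(classify_events(a, b)), 0)
  }
})

test_that("a multi-region pair yields multiple events", {
  a <- tx_struct("a", "+", c(0, 100), c(200, 300), c(400, 500), c(600, 700))
  b <- tx_struct("b", "+", c(50, 100), c(400, 500), c(600, 700))
  ev <- classify_events(a, b)
  expect_true(length(ev) >= 2)
  expect_true("exon_skipping" %in% ev)
  expect_true("tandem_5utr" %in% ev)
})

test_that("isoform-pair selection finds the opposite-direction extremes", {
  # two transcripts: the pair is forced
  m2 <- rbind(`0` = c(0.7, 0.3), `2` = c(0.4, 0.6))
  colnames(m2) <- c("t1", "t2")
  expect_identical(select_isoform_pair(m2), c("t2", "t1"))

  # argmax/argmin of the change vector
  m3 <- rbind(`0` = c(0.3, 0.45, 0.25), `2` = c(0.5, 0.3, 0.2))
  colnames(m3) <- c("t1", "t2", "t3")
  expect_identical(select_isoform_pair(m3), c("t1", "t2"))

  # brute-force oracle over group pairs for a 4-transcript, 3-group table
  set.seed(61)
  for (i in 1:10) {
    m <- matrix(rgamma(12, 3), 3, 4)
    m <- m / rowSums(m)
    colnames(m) <- paste0("t", 1:4)
    rownames(m) <- as.character(0:2)
    best <- NULL
    best_md <- -1
    for (i1 in 1:2) for (i2 in (i1 + 1):3) {
      md <- max(abs(m[i2, ] - m[i1, ]))
      if (md > best_md) {
        best_md <- md
        delta <- m[i2, ] - m[i1, ]
        best <- c(names(which.max(delta)), names(which.min(delta)))
      }
    }
    expect_identical(select_isoform_pair(m), best)
  }

  same <- rbind(`0` = c(0.5, 0.5), `2` = c(0.5, 0.5))
  colnames(same) <- c("t1", "t2")
  expect_error(select_isoform_pair(same), "opposite-direction")
})
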