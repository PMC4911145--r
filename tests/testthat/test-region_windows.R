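sizes <- c(chr1 = 1e7, chr2 = 5e6)

test_that("element validation enforces the length range and classes", {
  expect_error(elements("chr1", 1000, 1030, id = "tiny"), "length outside")
  expect_error(elements("chr1", 1000, 20000, id = "huge"), "length outside")
  expect_silent(elements("chr1", 1000, 1060))
  expect_error(elements("chr1", 1000, 2000, strand = "*"), "strand")
  expect_error(elements("chr1", 1000, 2000, class_label = "weird"),
               "class_label")
  # zero-width anchors allowed for controls only
  expect_silent(elements("chr1", 5000, 5000, class_label = "control"))
  expect_error(elements("chr1", 5000, 5000, class_label = "fixed"))
})

test_that("flank windows: plus strand, minus strand inversion, boundary drop", {
  els <- elements("chr1", c(100000, 100000, 500),
                  c(101000, 101000, 1500),
                  strand = c("+", "-", "+"), id = c("p", "m", "edge"))
  fw <- build_flanks(els, sizes, flank_kb = 32, window_kb = 1)
  p <- fw[fw$element_id == "p", ]
  expect_equal(nrow(p), 64)
  expect_equal(p$start[p$label == 1], 101000)
  expect_equal(p$end[p$label == 1], 102000)
  expect_equal(p$start[p$label == -1], 99000)
  expect_equal(p$start[p$label == -32], 100000 - 32000)
  m <- fw[fw$element_id == "m", ]
  expect_equal(p$start[p$label == 1], 101000)
  expect_equal(m$start[m$label == 1], 99000)     # inverted
  expect_equal(m$start[m$label == -1], 101000)
  # element too close to chromosome start is dropped with a reason
  expect_false("edge" %in% fw$element_id)
  expect_equal(attr(fw, "dropped")$reason, "flank_out_of_bounds")
})

test_that("orientation involution: flipping strand twice restores the curve", {
  set.seed(2)
  els_p <- elements("chr1", 200000, 201000, strand = "+", id = "e")
  els_m <- elements("chr1", 200000, 201000, strand = "-", id = "e")
  track <- data.frame(chrom = "chr1",
                      start = sort(sample(168000:233000, 50)))
  track$end <- track$start + sample(50:400, 50, replace = TRUE)
  fw_p <- build_flanks(els_p, sizes, 32, 1)
  fw_m <- build_flanks(els_m, sizes, 32, 1)
  cp <- quantify_content(track, fw_p)$values
  cm <- quantify_content(track, fw_m)$values
  # minus-strand curve is the reverse of the plus-strand curve
  expect_equal(unname(cm[1, ]), unname(rev(cp[1, ])))
})

test_that("gap and mutual flank-overlap filters follow the stated rules", {
  els <- elements("chr1", c(100000, 300000, 364000),
                  c(101000, 301000, 365000),
                  id = c("gapped", "pairA", "pairB"))
  # 400-bp gap inside gapped's upstream flank (> 320 bp -> excluded)
  gaps <- data.frame(chrom = "chr1", start = 90000, end = 90400)
  out <- filter_elements(els, gap_track = gaps)
  expect_true("gapped" %in% out$excluded$id)
  expect_equal(out$excluded$rule[out$excluded$id == "gapped"],
               "gap_overlap")
  # pairA downstream flank [301000,333000) overlaps pairB upstream flank
  # [332000,364000) by 1 kb -> both excluded (symmetric rule)
  expect_true(all(c("pairA", "pairB") %in% out$excluded$id))
  expect_equal(nrow(out$retained), 0)
  # isolated, gap-free elements are retained
  iso <- elements("chr2", 1e6, 1e6 + 1000, id = "iso")
  out2 <- filter_elements(iso, gap_track = gaps)
  expect_equal(out2$retained$id, "iso")
  expect_equal(nrow(out2$excluded), 0)
  # 320-bp gap overlap is tolerated (rule is strict >)
  gaps320 <- data.frame(chrom = "chr2", start = 1e6 - 320, end = 1e6)
  expect_equal(nrow(filter_elements(iso, gap_track = gaps320)$retained), 1)
  # chrY excluded by default
  sizes_y <- c(sizes, chrY = 1e6)
  ely <- elements("chrY", 2e5, 2e5 + 1000, id = "y")
  expect_equal(filter_elements(ely)$excluded$rule, "excluded_chromosome")
})

test_that("flank overlap threshold check via interval arithmetic", {
  # two elements 63 kb apart: 64-kb flanking spans overlap by ~1 kb
  e <- elements("chr1", c(200000, 200000 + 63000 + 1000),
                c(201000, 201000 + 63000 + 1000), id = c("a", "b"))
  out <- filter_elements(e)
  expect_setequal(out$excluded$id, c("a", "b"))
  # 65 kb apart: flanks just clear of each other, both retained
  e2 <- elements("chr1", c(200000, 200000 + 65000 + 1000),
                 c(201000, 201000 + 65000 + 1000), id = c("a", "b"))
  expect_equal(nrow(filter_elements(e2)$retained), 2)
})

test_that("control placement respects LTR and avoidance constraints", {
  small <- c(chr1 = 2e6)
  ctr <- make_controls(small, 5, seed = 4)
  expect_equal(nrow(ctr), 5)
  expect_true(all(ctr$class_label == "control"))
  expect_true(all(ctr$start == ctr$end))           # zero-width anchors
  # mutual non-overlap of the 64-kb regions
  reg <- data.frame(start = ctr$start - 32000, end = ctr$start + 32000)
  reg <- reg[order(reg$start), ]
  expect_true(all(reg$start[-1] >= reg$end[-nrow(reg)]))
  # reproducible
  expect_identical(make_controls(small, 5, seed = 4), ctr)
  # LTR covering the whole genome: impossible placement
  ltr_all <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  expect_error(make_controls(small, 2, ltr_track = ltr_all, seed = 1,
                             max_attempts = 200), "placement failed")
  # 50% LTR coverage (concentrated in one half, plus scattered remnants) at
  # 2% tolerance: verify every control per-base
  blocks <- seq(1.2e6, 2e6 - 4000, by = 4e4)
  ltr50 <- data.frame(chrom = "chr1",
                      start = c(0, blocks), end = c(1e6, blocks + 500))
  ctr2 <- make_controls(small, 3, ltr_track = ltr50,
                        max_ltr_fraction = 0.02, seed = 9,
                        max_attempts = 5000)
  for (i in seq_len(nrow(ctr2))) {
    ov <- oracle_content(ltr50, ctr2$start[i] - 32000,
                         ctr2$start[i] + 32000)
    expect_lte(ov, 0.02)
  }
})

test_that("content quantification: arithmetic, merging, per-base oracle", {
  els <- elements("chr1", 132000, 133000, id = "e")
  fw <- build_flanks(els, sizes, 32, 1)
  # single interval covering a quarter of window +1 = [133000,134000)
  tr <- data.frame(chrom = "chr1", start = 133100, end = 133350)
  expect_equal(unname(quantify_content(tr, fw)$values[1, "1"]), 0.25)
  # overlapping intervals are merged before coverage
  tr2 <- data.frame(chrom = "chr1", start = c(133000, 133400),
                    end = c(133600, 134000))
  expect_equal(unname(quantify_content(tr2, fw)$values[1, "1"]), 1.0)
  # 200 random intervals vs per-base oracle on every window
  set.seed(14)
  rnd <- data.frame(chrom = "chr1",
                    start = sample(99000:166000, 200, replace = TRUE))
  rnd$end <- rnd$start + sample(10:1500, 200, replace = TRUE)
  cmv <- quantify_content(rnd, fw)$values
  for (lab in colnames(cmv)) {
    w <- fw[fw$label == as.integer(lab), ]
    expect_equal(unname(cmv[1, lab]), oracle_content(rnd, w$start, w$end),
                 info = lab)
  }
  # sum rule: track plus its complement covers every window exactly once
  comp <- data.frame(chrom = "chr1",
                     start = c(0, rnd$end[order(rnd$start)]),
                     end = c(rnd$start[order(rnd$start)], sizes["chr1"]))
  comp <- comp[comp$start < comp$end, ]
  both <- quantify_content(rbind(rnd, comp), fw)$values
  expect_true(all(abs(both - 1) < 1e-12))
})

test_that("count quantification: start-binning, conservation, oracle", {
  els <- elements("chr1", 132000, 133000, id = "e")
  fw <- build_flanks(els, sizes, 32, 1)
  tr3 <- data.frame(chrom = "chr1", start = c(133010, 133500, 133900),
                    end = c(133020, 133510, 133910))
  expect_equal(unname(quantify_count(tr3, fw)$values[1, "1"]), 3)
  # motif straddling the +1/+2 boundary counts once, in +1 (its start)
  strad <- data.frame(chrom = "chr1", start = 133990, end = 134200)
  cmv <- quantify_count(strad, fw)$values
  expect_equal(unname(cmv[1, "1"]), 1)
  expect_equal(unname(cmv[1, "2"]), 0)
  expect_equal(sum(cmv), 1)
  # random motifs: per-window oracle and whole-region conservation
  set.seed(15)
  rnd <- data.frame(chrom = "chr1",
                    start = sample(100000:164999, 300, replace = TRUE))
  rnd$end <- rnd$start + 8
  cmv <- quantify_count(rnd, fw)$values
  for (lab in colnames(cmv)) {
    w <- fw[fw$label == as.integer(lab), ]
    expect_equal(unname(cmv[1, lab]), oracle_count(rnd, w$start, w$end))
  }
  # conservation over the flanks (the element body is not a window)
  expect_equal(sum(cmv), sum(rnd$start >= 100000 & rnd$start < 132000) +
                 sum(rnd$start >= 133000 & rnd$start < 165000))
})

test_that("weighted averages: arithmetic, identity, missing flag, oracle", {
  els <- elements("chr1", 132000, 133000, id = "e")
  fw <- build_flanks(els, sizes, 32, 1)
  tr <- data.frame(chrom = "chr1", start = c(133000, 133300),
                   end = c(133300, 133400), value = c(2, 4))
  expect_equal(unname(quantify_wa(tr, fw)$values[1, "1"]), 2.5)
  # uniform value across a window is returned exactly
  u <- data.frame(chrom = "chr1", start = 120000, end = 140000, value = 7)
  expect_equal(unname(quantify_wa(u, fw)$values[1, "1"]), 7)
  # windows without data are NA, then mean-imputed per region
  cmv <- quantify_wa(tr, fw)
  expect_true(is.na(cmv$values[1, "5"]))
  imp <- impute_wa_curves(cmv)
  expect_equal(unname(imp$values[1, "5"]), 2.5)
  expect_equal(sum(attr(imp, "imputed")), 63)
  # random valued intervals vs per-base oracle
  set.seed(16)
  rnd <- data.frame(chrom = "chr1",
                    start = sample(99000:166000, 150, replace = TRUE))
  rnd$end <- rnd$start + sample(100:3000, 150, replace = TRUE)
  rnd$value <- rnorm(150)
  cmv <- quantify_wa(rnd, fw)$values
  for (lab in colnames(cmv)) {
    w <- fw[fw$label == as.integer(lab), ]
    expect_equal(unname(cmv[1, lab]), oracle_wa(rnd, w$start, w$end))
  }
})

test_that("scalar quantification: rates over the region and distances", {
  els <- elements("chr1", c(132000, 500000), c(133000, 501000),
                  id = c("a", "b"))
  const <- data.frame(chrom = "chr1", start = 0, end = 1e6, value = 3.5)
  lm <- data.frame(chrom = "chr1", pos = c(132500, 0),
                   type = c("centromere", "telomere"))
  st <- quantify_scalars(els, rate_tracks = list(rate = const),
                         landmarks = lm)
  expect_equal(st$rate, c(3.5, 3.5))
  expect_equal(st$dist_to_centromere[1], 0)       # adjacent annotation
  expect_equal(st$dist_to_telomere[2], 500500)
  # random track: equality with whole-region per-base oracle
  set.seed(18)
  rnd <- data.frame(chrom = "chr1",
                    start = sample(90000:170000, 80, replace = TRUE))
  rnd$end <- rnd$start + sample(500:5000, 80, replace = TRUE)
  rnd$value <- runif(80)
  st2 <- quantify_scalars(els[1, ], rate_tracks = list(r = rnd))
  up <- oracle_wa(rnd, 100000, 132000)
  dn <- oracle_wa(rnd, 133000, 165000)
  # combine the two flanks per-base
  num <- 0; den <- 0
  for (rg in list(c(100000, 132000), c(133000, 165000)))
    for (i in seq_len(nrow(rnd))) {
      a <- max(rnd$start[i], rg[1]); b <- min(rnd$end[i], rg[2])
      if (a < b) { num <- num + rnd$value[i] * (b - a); den <- den + b - a }
    }
  expect_equal(st2$r, num / den)
})

test_that("malformed BED input reports the offending line", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t50\t40"), path)
  expect_error(read_bed(path), "line 2")
})
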