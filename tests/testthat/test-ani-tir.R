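# ANIb fragmentation/aggregation, species clustering, and terminal
# inverted repeat detection and trimming.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

test_that("genome fragmentation covers the sequence in near-equal pieces", {
  fr <- fragment_genome(strrep("A", 10000))
  expect_equal(nrow(fr), 1000L)
  expect_true(all(fr$length == 10L))
  expect_equal(fr$start[1], 1L)
  expect_equal(fr$end[1000], 10000L)
  expect_true(all(fr$start[-1] == fr$end[-1000] + 1L))  # contiguous

  fr2 <- fragment_genome(strrep("A", 10001))
  expect_equal(sum(fr2$length == 10L), 999L)
  expect_equal(sum(fr2$length == 11L), 1L)
  expect_equal(fr2$end[1000], 10001L)
  expect_true(max(fr2$length) - min(fr2$length) <= 1L)

  expect_error(fragment_genome(strrep("A", 999)), "shorter")
})

test_that("one-way ANIb averages best-hit identities above the filters", {
  frags <- tibble::tibble(
    fragment_id = c("f1", "f2", "f3", "f4"),
    start = 1L, end = 100L, length = 100L, seq = NA_character_
  )
  hit <- function(q, id, len = 100, bits = 200, s = "s1") {
    tibble::tibble(query_id = q, subject_id = s, pct_identity = id,
                   aln_length = as.integer(len), mismatch = 0L,
                   gapopen = 0L, qstart = 1L, qend = as.integer(len),
                   sstart = 1L, send = as.integer(len),
                   evalue = 1e-50, bitscore = bits)
  }
  # identities {80, 95}, full coverage -> mean 87.5
  expect_equal(anib_oneway(frags[1:2, ], rbind(hit("f1", 80), hit("f2", 95))),
               87.5)
  # a 25 % identity hit fails the 30 % floor and is excluded
  expect_equal(
    anib_oneway(frags[1:3, ],
                rbind(hit("f1", 80), hit("f2", 95), hit("f3", 25))),
    87.5)
  # 90 % identity but only 60 % coverage -> fragment excluded
  expect_equal(
    anib_oneway(frags[1:3, ],
                rbind(hit("f1", 80), hit("f2", 95), hit("f3", 90, len = 60))),
    87.5)
  # coverage is an exclusive bound: exactly 70 % does not qualify
  expect_equal(
    anib_oneway(frags[1:3, ],
                rbind(hit("f1", 80), hit("f2", 95), hit("f3", 90, len = 70))),
    87.5)
  # best hit per fragment picked by bitscore before filtering
  expect_equal(
    anib_oneway(frags[1, ],
                rbind(hit("f1", 80, bits = 300), hit("f1", 99, bits = 100))),
    80)
  # nothing qualifies -> undefined, not zero
  expect_true(is.na(anib_oneway(frags[1, ], hit("f1", 10))))
})

test_that("pairwise ANIb through blastn: self is 100, divergence lowers it", {
  withr::local_seed(31L)
  g <- rand_dna(60000)
  self <- anib_pair(g, g, "A", "A2")
  expect_equal(self$final, 100)
  expect_equal(self$final, (self$oneway_ab + self$oneway_ba) / 2)

  # ~2 % of substitutions: ANI near 98, definitely below 100
  chars <- strsplit(g, "")[[1]]
  pos <- sample(length(chars), 1200)
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  g2 <- paste(chars, collapse = "")
  div <- anib_pair(g, g2, "A", "B")
  expect_lt(div$final, 99.5)
  expect_gt(div$final, 95)
})

test_that("species clustering is single-linkage at the 96 % threshold", {
  ani <- tibble::tibble(
    genome_a = c("A", "A", "B"), genome_b = c("B", "C", "C"),
    final = c(97, 80, 80))
  cl <- cluster_species(ani, threshold = 96)
  expect_equal(cl$cluster[cl$genome_id == "A"],
               cl$cluster[cl$genome_id == "B"])
  expect_false(cl$cluster[cl$genome_id == "C"] ==
                 cl$cluster[cl$genome_id == "A"])
  # partition: every genome in exactly one cluster
  expect_setequal(cl$genome_id, c("A", "B", "C"))
  expect_equal(anyDuplicated(cl$genome_id), 0L)

  # all below threshold -> singletons
  lone <- cluster_species(dplyr::mutate(ani, final = c(90, 80, 80)))
  expect_equal(dplyr::n_distinct(lone$cluster), 3L)

  # chaining A-B, B-C joins all three even though A-C < 96
  chain <- cluster_species(dplyr::mutate(ani, final = c(97, 90, 97)))
  expect_equal(dplyr::n_distinct(chain$cluster), 1L)

  # representative = largest genome of the cluster
  cl2 <- cluster_species(ani, genome_sizes = c(A = 5e6, B = 9e6, C = 1e6))
  expect_true(cl2$representative[cl2$genome_id == "B"])
  expect_false(cl2$representative[cl2$genome_id == "A"])
  expect_true(cl2$representative[cl2$genome_id == "C"])
})

test_that("TIR detection finds planted repeats and ignores random ends", {
  withr::local_seed(41L)
  tir <- rand_dna(1000)
  mid <- rand_dna(8000)
  seq1 <- paste0(tir, mid, revcomp(tir))
  call <- detect_tir(seq1, min_len = 100)
  expect_gte(call$tir_length_bp, 1000L)
  expect_gte(call$pct_identity, 99)

  # random sequence: nothing at 99 % identity over >= 100 bp
  expect_equal(detect_tir(rand_dna(20000), min_len = 100)$tir_length_bp, 0L)

  # 2 mismatches in 1000 bp (99.8 %) still detected at the 99 % floor
  tir2 <- strsplit(tir, "")[[1]]
  for (i in c(400, 700)) {
    tir2[i] <- setdiff(c("A", "C", "G", "T"), tir2[i])[1]
  }
  seq2 <- paste0(paste(tir2, collapse = ""), mid, revcomp(tir))
  call2 <- detect_tir(seq2, min_len = 100)
  expect_gte(call2$tir_length_bp, 1000L)
  expect_lt(call2$pct_identity, 100)
  expect_gte(call2$pct_identity, 99)
})

test_that("TIR trimming removes one copy and is idempotent", {
  withr::local_seed(43L)
  seq0 <- rand_dna(10000)
  expect_equal(trim_tir(seq0, 0L), seq0)

  tir <- rand_dna(1000)
  seq1 <- paste0(tir, rand_dna(8000), revcomp(tir))
  trimmed <- trim_tir(seq1, 1000L)
  expect_equal(nchar(trimmed), 9000L)
  expect_equal(trimmed, substr(seq1, 1, 9000))
  # trimming leaves no detectable repeat behind
  expect_equal(detect_tir(trimmed, min_len = 100)$tir_length_bp, 0L)

  # genes entirely inside the removed right copy are dropped,
  # a straddling gene is dropped with a warning
  ch <- linear_chromosome(tibble::tibble(
    gene_id = c("left", "straddle", "inside"),
    start = c(100L, 8900L, 9200L),
    end = c(400L, 9100L, 9800L),
    strand = "+"), "G", length_bp = 10000L)
  expect_warning(res <- trim_tir(seq1, 1000L, chrom = ch), "straddle")
  expect_equal(res$chromosome$gene_id, "left")
  expect_equal(chrom_length(res$chromosome), 9000L)
})
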