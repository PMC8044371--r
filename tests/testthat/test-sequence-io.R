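test_that("FASTA records are read with case normalization and labels", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1 desc", "acgt", ">r2", "ACGT"), f)
  d <- read_fasta(f, task = "tA", label = 1)
  expect_equal(d$id, c("r1", "r2"))
  expect_equal(d$seq, c("ACGT", "ACGT"))
  expect_equal(d$label, c(1L, 1L))
  expect_equal(d$task, c("tA", "tA"))
})

test_that("alphabet policy is enforced: strict errors, skip drops and counts", {
  expect_equal(validate_seq("acGT"), "ACGT")
  expect_error(validate_seq("ACNT"), "position 3")
  expect_true(is.na(suppressMessages(validate_seq("ACNT", policy = "skip"))))
  v <- suppressMessages(validate_seqs(c("ACGT", "ACNT", "tttt"), policy = "skip"))
  expect_equal(v$seq, c("ACGT", "TTTT"))
  expect_equal(v$n_dropped, 1L)
  expect_equal(sum(v$keep) + v$n_dropped, 3L)

  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">badrec", "ANGT"), f)
  expect_error(read_fasta(f, "tA", 0), "badrec")
  d <- suppressMessages(read_fasta(f, "tA", 0, policy = "skip"))
  expect_equal(d$id, "ok")
})

test_that("empty or missing FASTA files error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f, "tA", 0), "empty")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa"), "tA", 0), "not found")
})

test_that("FASTA write/read round-trip preserves (id, seq) pairs", {
  set.seed(7)
  d <- data.frame(id = paste0("s", 1:50),
                  seq = random_dna(50, 41), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(d, f)
  back <- read_fasta(f, task = "t", label = 1)
  expect_equal(back$id, d$id)
  expect_equal(back$seq, d$seq)
})

make_manifest <- function(dir, tasks, n = 10L, len = 12L) {
  rows <- list()
  for (tn in tasks) {
    for (sp in c("train", "test")) {
      for (lab in c(0L, 1L)) {
        fn <- sprintf("%s_%s_%d.fasta", tn, sp, lab)
        write_fasta(stats::setNames(random_dna(n, len),
                                    paste0(tn, sp, lab, "_", seq_len(n))),
                    file.path(dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(task = tn, split = sp,
                                                label = lab, fasta_path = fn)
      }
    }
  }
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man
}

test_that("manifest loading counts records and balances classes", {
  dir <- withr::local_tempdir()
  set.seed(3)
  man <- make_manifest(dir, "tA", n = 10L)
  reg <- read_manifest(man)
  expect_s3_class(reg, "mt_registry")
  expect_length(reg$tasks, 1L)
  expect_equal(nrow(reg$tasks$tA$train), 20L)
  expect_equal(nrow(reg$tasks$tA$test), 20L)
  expect_true(is_balanced(reg))
  cts <- registry_counts(reg)
  expect_equal(sum(cts$n), 40L)
})

test_that("registry task order is name-sorted regardless of row order", {
  dir <- withr::local_tempdir()
  set.seed(4)
  man <- make_manifest(dir, c("zeta", "alpha", "mid"), n = 4L)
  # shuffle manifest rows
  m <- utils::read.delim(man)
  m <- m[rev(seq_len(nrow(m))), ]
  utils::write.table(m, man, sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- read_manifest(man)
  expect_equal(names(reg$tasks), c("alpha", "mid", "zeta"))
})

test_that("manifest schema violations are reported with the row", {
  dir <- withr::local_tempdir()
  set.seed(5)
  man <- make_manifest(dir, "tA", n = 4L)
  m <- utils::read.delim(man)
  m$split[2] <- "validation"
  utils::write.table(m, man, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(man), "row 2.*validation")

  m <- utils::read.delim(file.path(dir, "manifest.tsv"))
  m$split[2] <- "train"  # restore, then duplicate a row
  m <- rbind(m, m[1, ])
  utils::write.table(m, man, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(man), "duplicate")

  m <- m[1:4, ]
  m$fasta_path[1] <- "missing.fasta"
  utils::write.table(m, man, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(man), "not found")
})

test_that("single labeled TSV input builds the same registry shape", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(6)
  d <- data.frame(id = paste0("s", 1:8), task = rep(c("tB", "tA"), each = 4),
                  split = rep(c("train", "test"), 4),
                  label = rep(c(0L, 1L), 4), seq = random_dna(8, 10))
  utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- read_labeled_tsv(f)
  expect_equal(names(reg$tasks), c("tA", "tB"))
  expect_equal(nrow(reg$tasks$tA$train) + nrow(reg$tasks$tA$test), 4L)
})
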