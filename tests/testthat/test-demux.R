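test_that("MGI read headers parse into their fields", {
  id <- parse_mgi_read_id("@V300014293L2C001R0030000123/1")
  expect_equal(
    unlist(id[1, ]),
    c(flowcell = "V300014293", lane = "2", column = "1", row = "3",
      serial = "123", mate = "1")
  )
  id2 <- parse_mgi_read_id("@E100024783L1C012R0990000001/2")
  expect_equal(id2$column, 12L)
  expect_equal(id2$row, 99L)
  expect_equal(id2$serial, 1L)
  expect_equal(id2$mate, 2L)
  expect_error(parse_mgi_read_id("@SRR123.1 1"), "not in MGI format")
})

test_that("header grammar round-trips through compose/parse", {
  h <- mgidemux:::compose_mgi_read_id("V350096291", 1L, 5L, 17L, 42L, 2L)
  id <- parse_mgi_read_id(h)
  expect_equal(id$column, 5L)
  expect_equal(id$row, 17L)
  expect_equal(id$serial, 42L)
  expect_equal(id$mate, 2L)
})

test_that("extract_barcode slices the template fields from the read tail", {
  e <- extract_barcode("AAAATTTTGGTTACGT", template = "i5rc.4:i7.4")
  expect_equal(e$i5_obs, "AACC")
  expect_equal(e$i7_obs, "ACGT")
  expect_null(e$umi)
  expect_equal(e$trimmed$sequence, "AAAATTTT")

  e2 <- extract_barcode("CCCCACGTAACC", template = "i7.4:i5.4")
  expect_equal(e2$i7_obs, "ACGT")
  expect_equal(e2$i5_obs, "AACC")
  expect_equal(e2$trimmed$sequence, "CCCC")

  # barcode-only read: empty trimmed read is legal
  e3 <- extract_barcode("ACGT", template = "i7.4")
  expect_equal(e3$i7_obs, "ACGT")
  expect_equal(e3$trimmed$sequence, "")

  expect_error(extract_barcode("ACG", template = "i7.4"), "shorter")
})

test_that("extract_barcode trims quality alongside sequence", {
  e <- extract_barcode("AAAACCCC", quality = "IIII!!!!", template = "i7.4")
  expect_equal(e$trimmed$quality, "IIII")
  expect_equal(nchar(e$trimmed$sequence), nchar(e$trimmed$quality))
})

test_that("assign_read applies best-match / ambiguous / undetermined rules", {
  lk1 <- build_lookup(make_sheet("S1", "AAAA"), m7 = 1)
  a <- assign_read("AATA", table = lk1)
  expect_equal(a$verdict, "sample")
  expect_equal(a$sample_id, "S1")
  expect_equal(a$d7, 1L)

  lk2 <- build_lookup(make_sheet(c("S1", "S2"), c("AAAA", "AAAT")), m7 = 1)
  expect_equal(assign_read("AAAG", table = lk2)$verdict, "ambiguous")
  expect_equal(assign_read("GGGG", table = lk2)$verdict, "undetermined")
})

test_that("output headers follow the declared dialects", {
  id <- data.frame(flowcell = "V300014293", lane = 2L, column = 1L,
                   row = 3L, serial = 123L, mate = 1L)
  expect_equal(
    format_output_id(id, "illumina", index_annot = "ACGT+AACC"),
    "@V300014293:1:V300014293:2:1003:123:1 1:N:0:ACGT+AACC"
  )
  expect_equal(
    format_output_id(id, "illumina", umi = "TTTT", index_annot = "ACGT+AACC"),
    "@V300014293:1:V300014293:2:1003:123:1:TTTT 1:N:0:ACGT+AACC"
  )
  orig <- "@V300014293L2C001R0030000123/1"
  expect_equal(format_output_id(id, "mgi", original = orig), orig)
  expect_equal(
    format_output_id(id, "mgi", umi = "TTTT", original = orig),
    "@V300014293L2C001R0030000123#TTTT/1"
  )
})

test_that("output file naming follows the declared dialects", {
  expect_equal(output_path("SampleA", 1, 1, 1, "illumina"),
               "SampleA_S1_L001_R1_001.fastq.gz")
  expect_equal(output_path("SampleA", 1, 2, 2, "mgi", flowcell = "V300014293"),
               "V300014293_L02_SampleA_2.fq.gz")
  expect_equal(output_path("Undetermined", 0, 1, 1, "illumina"),
               "Undetermined_S0_L001_R1_001.fastq.gz")
})

test_that("a clean paired-end run demultiplexes perfectly with order kept", {
  dir <- withr::local_tempdir()
  sim <- simulate_run(dir, n_samples = 3, reads_per_sample = 40,
                      umi_len = 6, seed = 101)
  out <- file.path(dir, "out")
  run <- demultiplex_run(sim$r1, sim$r2, sim$sample_sheet,
                         template = sim$template, output_dir = out,
                         keep_assignments = TRUE)
  truth <- read.delim(sim$truth)
  a <- attr(run, "assignments")

  # exact recovery of the truth table
  expect_equal(a$sample_id[order(a$serial)],
               truth$true_sample[order(truth$serial)])
  expect_true(all(a$verdict == "sample"))
  expect_equal(sum(a$d7 + a$d5), 0L)
  expect_equal(a$umi[order(a$serial)], truth$umi[order(truth$serial)])

  # conservation
  m <- run$merged
  expect_equal(sum(m$reads) + m$undetermined + m$ambiguous, 120L)

  # order: serials strictly increasing within every output file
  for (f in list.files(out, pattern = "fastq.gz$", full.names = TRUE)) {
    fq <- read_fastq_gz(f)
    if (length(fq$header) == 0) next
    serial <- illumina_serial(fq$header)
    expect_true(all(diff(serial) > 0), info = f)
  }

  # trimming: R2 lost exactly the barcode, R1 untouched
  r2out <- read_fastq_gz(file.path(out, "S01_S1_L001_R2_001.fastq.gz"))
  expect_true(all(nchar(r2out$sequence) == 100L))
  expect_true(all(nchar(r2out$sequence) == nchar(r2out$quality)))
  r1out <- read_fastq_gz(file.path(out, "S01_S1_L001_R1_001.fastq.gz"))
  expect_true(all(nchar(r1out$sequence) == 100L))

  # UMI present in both mates' headers
  expect_true(all(grepl("^@[^ ]+:[ACGT]{6} ", r1out$header)))
  expect_true(all(grepl("^@[^ ]+:[ACGT]{6} ", r2out$header)))
})

test_that("outputs are well-formed gzip FASTQ readable by ShortRead", {
  dir <- withr::local_tempdir()
  sim <- simulate_run(dir, n_samples = 2, reads_per_sample = 25, seed = 5)
  out <- file.path(dir, "out")
  demultiplex_run(sim$r1, sim$r2, sim$sample_sheet, template = sim$template,
                  output_dir = out)
  f <- file.path(out, "S01_S1_L001_R2_001.fastq.gz")
  fq <- ShortRead::readFastq(f)
  expect_gt(length(fq), 0L)
  expect_true(all(ShortRead::width(fq) == 100L))
})

test_that("injected single errors are tolerated at m=1 but not at m=0", {
  dir <- withr::local_tempdir()
  sim <- simulate_run(dir, n_samples = 3, reads_per_sample = 30,
                      errors_per_index = 1, seed = 17,
                      min_index_distance = 3)
  run1 <- demultiplex_run(sim$r1, sim$r2, sim$sample_sheet,
                          template = sim$template, m7 = 1, m5 = 1,
                          output_dir = file.path(dir, "m1"),
                          keep_assignments = TRUE)
  a1 <- attr(run1, "assignments")
  truth <- read.delim(sim$truth)
  expect_true(all(a1$verdict == "sample"))
  expect_equal(a1$sample_id[order(a1$serial)], truth$true_sample)
  expect_true(all(a1$d7 == 1L & a1$d5 == 1L))

  run0 <- demultiplex_run(sim$r1, sim$r2, sim$sample_sheet,
                          template = sim$template, m7 = 0, m5 = 0,
                          output_dir = file.path(dir, "m0"))
  expect_equal(run0$merged$undetermined, 90L)
  expect_equal(sum(run0$merged$reads), 0L)
})

test_that("single-end runs carry the barcode on the R1 tail", {
  dir <- withr::local_tempdir()
  sim <- simulate_run(dir, n_samples = 2, reads_per_sample = 20,
                      paired = FALSE, seed = 23)
  out <- file.path(dir, "out")
  run <- demultiplex_run(sim$r1, sample_sheet = sim$sample_sheet,
                         template = sim$template, output_dir = out)
  expect_equal(sum(run$merged$reads), 40L)
  r1out <- read_fastq_gz(file.path(out, "S01_S1_L001_R1_001.fastq.gz"))
  expect_true(all(nchar(r1out$sequence) == 100L))  # barcode trimmed
})

test_that("MGI dialect keeps headers verbatim and MGI-style names", {
  dir <- withr::local_tempdir()
  sim <- simulate_run(dir, n_samples = 2, reads_per_sample = 15, seed = 31,
                      flowcell = "V350000042")
  out <- file.path(dir, "out")
  demultiplex_run(sim$r1, sim$r2, sim$sample_sheet, template = sim$template,
                  dialect = "mgi", output_dir = out)
  f <- file.path(out, "V350000042_L01_S01_2.fq.gz")
  expect_true(file.exists(f))
  fq <- read_fastq_gz(f)
  expect_true(all(grepl("^@V350000042L1C[0-9]{3}R[0-9]{3}[0-9]+/2$",
                        fq$header)))
  # headers verbatim = still present in the simulator input
  input <- read_fastq_gz(sim$r2)
  expect_true(all(fq$header %in% input$header))
})

test_that("paired-file desynchronization is reported with the read ordinal", {
  dir <- withr::local_tempdir()
  h1 <- c("@FCX100L1C001R0010000001/1", "@FCX100L1C001R0010000002/1")
  h2 <- c("@FCX100L1C001R0010000001/2", "@FCX100L1C001R00100000099/2")
  f1 <- write_fastq_gz(file.path(dir, "r1.fq.gz"), h1,
                       c("AAAACCCC", "AAAACCCC"))
  f2 <- write_fastq_gz(file.path(dir, "r2.fq.gz"), h2,
                       c("GGGGACGT", "GGGGACGT"))
  sheet <- make_sheet("S1", "ACGT")
  expect_error(
    demultiplex_run(f1, f2, sheet, template = "i7.4",
                    output_dir = file.path(dir, "out")),
    "desynchronized at read 2"
  )
})

test_that("mixed lanes in one file error unless a lane label is forced", {
  dir <- withr::local_tempdir()
  h <- c("@FCX100L1C001R0010000001/1", "@FCX100L2C001R0010000002/1")
  f1 <- write_fastq_gz(file.path(dir, "r1.fq.gz"), h,
                       c("GGGGACGT", "GGGGACGT"))
  sheet <- make_sheet("S1", "ACGT")
  expect_error(
    demultiplex_run(f1, sample_sheet = sheet, template = "i7.4",
                    output_dir = file.path(dir, "out")),
    "mixed lanes"
  )
  run <- demultiplex_run(f1, sample_sheet = sheet, template = "i7.4",
                         output_dir = file.path(dir, "out2"), lane = 7)
  expect_equal(sum(run$merged$reads), 2L)
  expect_true(file.exists(file.path(dir, "out2",
                                    "S1_S1_L007_R1_001.fastq.gz")))
})

test_that("ambiguous reads are counted separately and routed as configured", {
  dir <- withr::local_tempdir()
  # observation AAAG sits at distance 1 from both samples
  h <- "@FCX100L1C001R0010000001/1"
  f1 <- write_fastq_gz(file.path(dir, "r1.fq.gz"), h, "CCCCAAAG")
  sheet <- make_sheet(c("S1", "S2"), c("AAAA", "AAAT"))
  run <- demultiplex_run(f1, sample_sheet = sheet, template = "i7.4",
                         output_dir = file.path(dir, "out"))
  expect_equal(run$merged$ambiguous, 1L)
  expect_equal(run$merged$undetermined, 0L)
  expect_true(file.exists(file.path(dir, "out",
                                    "Undetermined_S0_L001_R1_001.fastq.gz")))
  run2 <- demultiplex_run(f1, sample_sheet = sheet, template = "i7.4",
                          output_dir = file.path(dir, "out2"),
                          separate_ambiguous = TRUE)
  expect_true(file.exists(file.path(dir, "out2",
                                    "Ambiguous_S0_L001_R1_001.fastq.gz")))
})

test_that("per-record template overrides demultiplex mixed libraries", {
  dir <- withr::local_tempdir()
  # S1 uses a plain 4 bp i7 tail; S2 carries a 4 bp UMI after its i7
  sheet <- make_sheet(c("S1", "S2"), c("ACGT", "TTAA"),
                      template = c("i7.4", "i7.4:um.4"))
  h <- sprintf("@FCX100L1C001R001%07d/1", 1:4)
  seqs <- c(
    paste0("CCCCCCCC", "ACGT"),          # S1: bio + i7
    paste0("GGGG", "TTAA", "ACCA"),      # S2: bio + i7 + UMI
    paste0("CCCCCCCC", "ACGA"),          # S1 with 1 mismatch
    paste0("AAAATTTT", "GGGG")           # matches neither
  )
  f1 <- write_fastq_gz(file.path(dir, "r1.fq.gz"), h, seqs)
  run <- demultiplex_run(f1, sample_sheet = sheet,
                         output_dir = file.path(dir, "out"),
                         keep_assignments = TRUE)
  a <- attr(run, "assignments")
  expect_equal(a$verdict, c("sample", "sample", "sample", "undetermined"))
  expect_equal(a$sample_id[1:3], c("S1", "S2", "S1"))
  expect_equal(a$umi[2], "ACCA")
  # S2's read lost its 8 bp barcode (i7 + UMI), S1's only 4 bp
  s2 <- read_fastq_gz(file.path(dir, "out", "S2_S2_L001_R1_001.fastq.gz"))
  expect_equal(nchar(s2$sequence), 4L)
  s1 <- read_fastq_gz(file.path(dir, "out", "S1_S1_L001_R1_001.fastq.gz"))
  expect_equal(nchar(s1$sequence), c(8L, 8L))
})
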