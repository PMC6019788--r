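#' Simulate sequencing reads and alignments with known counting truth
#'
#' Writes a self-contained toy RNA-seq fixture into `dir`: a paired FASTQ
#' file pair crafted so that every branch of the read filter is exercised
#' (N-content, 3-of-5 quality-window trimming, minimum-length), a GFF3 file
#' of toy gene models (multi-exon genes on both strands, including a pair of
#' overlapping genes), and one SAM file per sample whose alignments have
#' known exon-containment fates: counted, boundary-crossing, intron-spanning
#' (N CIGAR), low-MAPQ, multi-mapping (NH > 1), ambiguous (two overlapping
#' genes), and intergenic.
#'
#' Sequences are synthetic (the alignments are never re-derived from the
#' reads); coordinates are 1-based closed as in GFF3.
#'
#' @param config A [sim_config()] object (only the seed is used).
#' @param dir Directory the files are written to.
#' @return A list with file paths (`fastq_1`, `fastq_2`, `sam`, `gff3`) and
#'   ground truth: `truth_counts` (tibble gene_id x sample), `truth_reads`
#'   (expected surviving FASTQ fragment ids and lengths), and `truth_report`
#'   (expected per-sample counting category totals).
#' @export
simulate_read_experiment <- function(config = sim_config(), dir = tempdir()) {
  validate_sim_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  gff3 <- file.path(dir, "toy_models.gff3")
  write_toy_gene_models(gff3)

  fq <- write_toy_fastq(dir)
  sams <- write_toy_sam(dir)

  list(
    fastq_1 = fq$fastq_1, fastq_2 = fq$fastq_2,
    sam = sams$paths, gff3 = gff3,
    truth_counts = sams$truth_counts,
    truth_reads = fq$truth,
    truth_report = sams$truth_report
  )
}

# Toy gene models: geneA (chr1 +, 3 exons), geneB (chr1 -, 2 exons),
# geneC/geneD (chr1 +, overlapping single-exon genes), geneE (chr2 +, 2 exons).
toy_gene_exons <- function() {
  tibble(
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB",
                "geneC", "geneD", "geneE", "geneE"),
    seqnames = c(rep("chr1", 7), "chr2", "chr2"),
    start = c(1001, 1501, 2001, 3001, 3601, 5001, 5201, 1001, 2001),
    end   = c(1200, 1700, 2200, 3300, 3800, 5400, 5600, 1400, 2400),
    strand = c("+", "+", "+", "-", "-", "+", "+", "+", "+")
  )
}

write_toy_gene_models <- function(path) {
  ex <- toy_gene_exons()
  exons <- GenomicRanges::GRanges(
    seqnames = ex$seqnames,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand,
    type = "exon",
    gene_id = ex$gene_id
  )
  genes <- unlist(range(GenomicRanges::split(exons, exons$gene_id)))
  genes$type <- "gene"
  genes$gene_id <- names(genes)
  names(genes) <- NULL
  gr <- c(genes, exons)
  gr$ID <- ifelse(gr$type == "gene", gr$gene_id,
                  paste0(gr$gene_id, ":exon", seq_along(gr)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# FASTQ fixture: fragment ids encode the intended filter fate.
write_toy_fastq <- function(dir) {
  q40 <- function(n) strrep("I", n)           # Phred+33, Q40
  lowq <- "+"                                  # Q10 < 20
  seq_n <- function(n) strrep("A", n)

  mk_qual <- function(len, low_at) {
    q <- rep("I", len)
    q[low_at] <- lowq
    paste(q, collapse = "")
  }

  reads <- list(
    # clean pair, untouched
    list(id = "frag_clean", s1 = seq_n(100), q1 = q40(100),
         s2 = seq_n(100), q2 = q40(100)),
    # R1 has 7 N -> whole pair dropped
    list(id = "frag_7n", s1 = paste0(strrep("N", 7), seq_n(93)), q1 = q40(100),
         s2 = seq_n(100), q2 = q40(100)),
    # 6 N is below the limit -> kept
    list(id = "frag_6n", s1 = paste0(strrep("N", 6), seq_n(94)), q1 = q40(100),
         s2 = seq_n(100), q2 = q40(100)),
    # R1 low quality at 50:52; first 5-window with >=3 low starts at 48 -> 47 nt
    list(id = "frag_trim47", s1 = seq_n(100), q1 = mk_qual(100, 50:52),
         s2 = seq_n(100), q2 = q40(100)),
    # R1 low quality from position 10 on -> trimmed far below 41 -> pair dropped
    list(id = "frag_short", s1 = seq_n(100), q1 = mk_qual(100, 10:100),
         s2 = seq_n(100), q2 = q40(100)),
    # R2 low at 44:46; first window with 3 low starts at 42 -> exactly 41 nt kept
    list(id = "frag_trim41", s1 = seq_n(100), q1 = q40(100),
         s2 = seq_n(100), q2 = mk_qual(100, 44:46))
  )

  f1 <- file.path(dir, "toy_reads_1.fastq")
  f2 <- file.path(dir, "toy_reads_2.fastq")
  write_one <- function(path, mate) {
    lines <- unlist(lapply(reads, function(r) {
      c(paste0("@", r$id), r[[paste0("s", mate)]], "+", r[[paste0("q", mate)]])
    }))
    writeLines(lines, path)
  }
  write_one(f1, 1)
  write_one(f2, 2)

  truth <- tibble(
    id = c("frag_clean", "frag_6n", "frag_trim47", "frag_trim41"),
    length_1 = c(100L, 100L, 47L, 100L),
    length_2 = c(100L, 100L, 100L, 41L)
  )
  list(fastq_1 = f1, fastq_2 = f2, truth = truth)
}

# One properly-paired SAM record pair.
sam_pair <- function(qname, rname, pos1, cigar1, pos2, cigar2,
                     mapq = 60L, nh = 1L) {
  len <- function(cig) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cig)[[1]]
    parts <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    sum(vapply(parts, function(p) {
      n <- as.integer(sub("[MIDNSHP=X]", "", p))
      if (grepl("[MIS=X]", p)) n else 0L
    }, integer(1)))
  }
  l1 <- len(cigar1); l2 <- len(cigar2)
  tlen <- pos2 + l2 - pos1
  mk <- function(flag, pos, cigar, mpos, tl, l) {
    paste(qname, flag, rname, pos, mapq, cigar, "=", mpos, tl,
          strrep("A", l), strrep("I", l), paste0("NH:i:", nh), sep = "\t")
  }
  c(mk(99L, pos1, cigar1, pos2, tlen, l1),
    mk(147L, pos2, cigar2, pos1, -tlen, l2))
}

write_toy_sam <- function(dir) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:chr1\tLN:10000",
              "@SQ\tSN:chr2\tLN:5000")

  # scenario -> generator of SAM line pairs
  scen <- list(
    A_exon2    = function(q) sam_pair(q, "chr1", 1501, "60M", 1601, "60M"),
    A_njunc    = function(q) sam_pair(q, "chr1", 1651, "50M300N50M", 2051, "60M"),
    A_boundary = function(q) sam_pair(q, "chr1", 1151, "100M", 1501, "60M"),
    B_exon     = function(q) sam_pair(q, "chr1", 3001, "60M", 3101, "60M"),
    low_mapq   = function(q) sam_pair(q, "chr1", 1501, "60M", 1601, "60M", mapq = 20L),
    multimap   = function(q) sam_pair(q, "chr1", 1501, "60M", 1601, "60M", nh = 2L),
    ambiguous  = function(q) sam_pair(q, "chr1", 5201, "60M", 5301, "60M"),
    C_unique   = function(q) sam_pair(q, "chr1", 5001, "60M", 5101, "60M"),
    D_unique   = function(q) sam_pair(q, "chr1", 5401, "60M", 5501, "60M"),
    E_exon1    = function(q) sam_pair(q, "chr2", 1001, "60M", 1101, "60M"),
    E_njunc    = function(q) sam_pair(q, "chr2", 1351, "50M600N50M", 2001, "60M"),
    intergenic = function(q) sam_pair(q, "chr1", 8001, "60M", 8101, "60M")
  )

  plan <- list(
    case01 = c(A_exon2 = 2, A_njunc = 1, A_boundary = 1, B_exon = 2, low_mapq = 1,
               multimap = 1, ambiguous = 1, C_unique = 1, D_unique = 1,
               E_exon1 = 1, E_njunc = 1, intergenic = 1),
    ctrl01 = c(A_exon2 = 1, B_exon = 1, low_mapq = 1, ambiguous = 1,
               C_unique = 2, E_exon1 = 1)
  )

  paths <- character(0)
  for (s in names(plan)) {
    lines <- header
    i <- 0L
    for (nm in names(plan[[s]])) {
      for (k in seq_len(plan[[s]][[nm]])) {
        i <- i + 1L
        lines <- c(lines, scen[[nm]](sprintf("%s_%s_%02d", s, nm, k)))
      }
    }
    p <- file.path(dir, paste0(s, ".sam"))
    writeLines(lines, p)
    paths[s] <- p
  }

  truth_counts <- tibble(
    gene_id = c("geneA", "geneB", "geneC", "geneD", "geneE"),
    case01 = c(3L, 2L, 1L, 1L, 2L),
    ctrl01 = c(1L, 1L, 2L, 0L, 1L)
  )
  truth_report <- tibble(
    sample_id = c("case01", "ctrl01"),
    total = c(14L, 7L),
    counted = c(9L, 5L),
    ambiguous = c(1L, 1L),
    low_mapq = c(1L, 1L),
    multimapped = c(1L, 0L),
    not_contained = c(2L, 0L)
  )
  list(paths = paths, truth_counts = truth_counts, truth_report = truth_report)
}
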