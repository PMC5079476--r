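# Tiny in-code fixtures shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 3-gene, 3-experiment expression compendium built from explicit samples
tiny_expression_compendium <- function(pseudocount = 1, log_base = 2) {
  s1 <- expression_sample("e1", c("g1", "g2", "g3"), c(3, 0, 7))
  s2 <- expression_sample("e2", c("g1", "g2", "g3"), c(1, 15, 0))
  s3 <- expression_sample("e3", c("g1", "g2", "g3"), c(3, 1, 6))
  md <- data.frame(experiment_id = c("e1", "e2", "e3"),
                   cell_type = c("a", "b", "a"),
                   factor = c("X", "X", "Y"), stringsAsFactors = FALSE)
  list(samples = list(s1, s2, s3), metadata = md,
       comp = build_expression_compendium(list(s1, s2, s3), md,
                                          pseudocount, log_base))
}

# two peak samples on two chromosomes with a known universe
tiny_peak_compendium <- function() {
  s1 <- peak_sample("p1", data.frame(chrom = c("chr1", "chr1", "chr2"),
                                     start = c(100, 500, 30),
                                     end = c(200, 700, 80)))
  s2 <- peak_sample("p2", data.frame(chrom = c("chr1", "chr2"),
                                     start = c(150, 400),
                                     end = c(260, 450)))
  md <- data.frame(experiment_id = c("p1", "p2"),
                   cell_type = c("a", "b"), stringsAsFactors = FALSE)
  list(samples = list(s1, s2), metadata = md,
       comp = build_peak_compendium(list(s1, s2), md))
}
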