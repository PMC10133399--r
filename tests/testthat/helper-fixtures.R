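# Small on-disk fixtures written at test time.

write_tiny_expression <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene\tS1\tS2\tS3\tS4",
               "G1\t1.5\t2.5\t3.5\t4.5",
               "G2\t0.1\t0.2\t0.3\t0.4",
               "G3\t5\t6\t7\t8"), path)
  path
}

write_tiny_metadata <- function(path = tempfile(fileext = ".tsv"),
                                labels = c("A", "A", "A", "B", "B", "C")) {
  writeLines(c("sample\tcondition",
               sprintf("S%d\t%s", seq_along(labels), labels)), path)
  path
}

write_tiny_network <- function(path = tempfile(fileext = ".tsv"),
                               rows = c("G1\tG2\tactivation\tFALSE",
                                        "G2\tG3\tactivation\tFALSE")) {
  writeLines(c("source\ttarget\ttype\tdirected", rows), path)
  path
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
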