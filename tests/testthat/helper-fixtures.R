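# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fix_ref <- function() memo("ref", synthetic_reference_cluster())

# one planted genome + its scan, per named event case
fix_case <- function(name, events, seed = 101, ...) {
  memo(paste0("case_", name), {
    ref <- fix_ref()
    pg <- plant_genome(ref$cluster, events = events, seed = seed,
                       genome_id = name, ...)
    list(pg = pg, arch = scan_genome(pg$genome, ref))
  })
}

fix_intact <- function() {
  fix_case("intact", list(ev_diverge(0.85)))
}

write_fasta <- function(headers, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}
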