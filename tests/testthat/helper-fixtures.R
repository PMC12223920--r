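# Programmatic fixtures: a minimal Bruker TopSpin processed-1D directory
# written at test time (binary 1r + JCAMP-style procs/acqus).

write_bruker_fixture <- function(dir, intensity, si = length(intensity),
                                 sw_ppm = 400, offset = 200, sf = 100,
                                 dtypp = 0L, nc_proc = 0L, byte_order = 0L,
                                 ns = 64L, masr_hz = 10000,
                                 drop_fields = character()) {
  pdir <- file.path(dir, "pdata", "1")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  params <- c(SI = si, SW_p = sw_ppm * sf, SF = sf, OFFSET = offset,
              BYTORDP = byte_order, DTYPP = dtypp, NC_proc = nc_proc)
  params <- params[setdiff(names(params), drop_fields)]
  writeLines(c("##TITLE= Parameter file, TopSpin-style",
               sprintf("##$%s= %s", names(params), params),
               "##END="),
             file.path(pdir, "procs"))
  writeLines(c("##TITLE= acquisition parameters",
               sprintf("##$NS= %d", ns),
               sprintf("##$MASR= %d", masr_hz),
               "##END="),
             file.path(dir, "acqus"))
  con <- file(file.path(pdir, "1r"), "wb")
  on.exit(close(con))
  endian <- if (byte_order == 1L) "big" else "little"
  if (dtypp == 2L) {
    writeBin(as.numeric(intensity), con, size = 8L, endian = endian)
  } else {
    writeBin(as.integer(round(intensity / 2^nc_proc)), con, size = 4L,
             endian = endian)
  }
  invisible(dir)
}
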