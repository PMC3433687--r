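# The packaged reference set of 79 experimentally determined hotspot windows
# (SR/RS-rich Arabidopsis regions) used as the positive training material.
# Shipped as two read-only text files under inst/extdata and checksummed.

REFERENCE_MD5 <- c(hotspot_windows.fasta = "c6acf66545a3eca38390374ffb030754",
                   hotspot_sites.tsv     = "c8ed4685c3a40704e6a710902fb25164")

#' Load the packaged reference hotspot set
#'
#' 79 experimentally determined hotspot windows on 75 Arabidopsis proteins:
#' for each record the padded window sequence, its 0-based start on the
#' source protein, and the 0-based positions of the phosphorylation sites.
#' One record (AT4G07523.1) lacks a printed window start in the source data;
#' its start is 0, as reproduced by the padding rule.
#'
#' @param check_md5 verify the fixture checksums before loading.
#' @return data frame with columns `protein_id`, `window_start`,
#'   `site_positions` (comma-joined, 0-based, protein coordinates),
#'   `window_sequence`, `hotspot_id`.
#' @export
reference_hotspots <- function(check_md5 = TRUE) {
  fa <- system.file("extdata", "hotspot_windows.fasta", package = "hotspotter",
                    mustWork = TRUE)
  tsv <- system.file("extdata", "hotspot_sites.tsv", package = "hotspotter",
                     mustWork = TRUE)
  if (check_md5) {
    got <- tools::md5sum(c(fa, tsv))
    names(got) <- basename(names(got))
    if (!identical(unname(got[names(REFERENCE_MD5)]), unname(REFERENCE_MD5)))
      stop("reference hotspot fixture checksum mismatch; files were modified")
  }
  fasta <- read_fasta(fa)
  sites <- utils::read.delim(tsv, colClasses = c("character", "integer", "character"))
  key <- paste0(sites$protein_id, "|", sites$window_start)
  m <- match(key, fasta$id)
  stopifnot(!anyNA(m))
  data.frame(protein_id = sites$protein_id,
             window_start = sites$window_start,
             site_positions = sites$site_positions,
             window_sequence = fasta$sequence[m],
             hotspot_id = key)
}

#' Validate the reference hotspot set against the hotspot definition
#'
#' Asserts, per record: at least `min_sites` sites, all neighbor gaps at most
#' `max_gap`, every site position landing on an S, T or Y of the window
#' sequence at `position - window_start` (0-based), and a window of at least
#' `min_len` residues.
#'
#' @param hotspots data frame as returned by [reference_hotspots()] (any
#'   table with the same columns can be checked, e.g. a corrupted copy in a
#'   negative control).
#' @param min_sites,max_gap,min_len hotspot definition parameters.
#' @return list with `ok` (logical), `failures` (data frame naming each
#'   offending record and the violated rule), `n_records`, `n_proteins`,
#'   `max_sites`, `max_sites_record`.
#' @export
validate_table <- function(hotspots, min_sites = 4L, max_gap = 10L,
                           min_len = 17L) {
  fail <- list()
  site_list <- parse_site_positions(hotspots$site_positions)
  for (i in seq_len(nrow(hotspots))) {
    s <- site_list[[i]]
    st <- hotspots$window_start[i]
    sq <- hotspots$window_sequence[i]
    L <- nchar(sq)
    rules <- character(0)
    if (length(s) < min_sites) rules <- c(rules, "too few sites")
    if (any(diff(s) > max_gap)) rules <- c(rules, "neighbor gap > max_gap")
    if (L < min_len) rules <- c(rules, "window shorter than min_len")
    rel <- s - st
    if (any(rel < 0L | rel >= L)) {
      rules <- c(rules, "site outside window")
    } else {
      res <- substring(sq, rel + 1L, rel + 1L)
      if (!all(res %in% c("S", "T", "Y")))
        rules <- c(rules, "site not on S/T/Y")
    }
    if (length(rules))
      fail[[length(fail) + 1L]] <- data.frame(
        hotspot_id = hotspots$hotspot_id[i], rule = paste(rules, collapse = "; "))
  }
  failures <- if (length(fail)) do.call(rbind, fail) else
    data.frame(hotspot_id = character(0), rule = character(0))
  n_sites <- lengths(site_list)
  list(ok = nrow(failures) == 0L,
       failures = failures,
       n_records = nrow(hotspots),
       n_proteins = length(unique(hotspots$protein_id)),
       max_sites = max(n_sites),
       max_sites_record = hotspots$hotspot_id[which.max(n_sites)])
}
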