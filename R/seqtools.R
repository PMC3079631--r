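AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Protein sequence container
#'
#' @param id Sequence identifier.
#' @param residues Uppercase amino-acid string (20-letter alphabet plus X).
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues) {
  residues <- toupper(residues)
  if (nchar(residues) == 0) stop("empty sequence")
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0)
    stop("invalid residue(s): ", paste(bad, collapse = ", "))
  structure(list(id = as.character(id), residues = residues),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf(">%s (%d aa)\n%s\n", x$id, nchar(x$residues), x$residues))
  invisible(x)
}

#' Parse a mutant construct name into point-mutation specs
#'
#' Construct names follow the `H53A/G54H/T85A` convention: slash-separated
#' tokens of wild-type residue, 1-based position, new residue. `"WT"` parses
#' to an empty spec list.
#'
#' @param name Construct name string.
#' @return A data frame with columns `wt`, `pos`, `new` (zero rows for WT).
#' @examples
#' parse_construct_name("H53A/G54H/T85A")
#' @export
parse_construct_name <- function(name) {
  empty <- data.frame(wt = character(), pos = integer(), new = character(),
                      stringsAsFactors = FALSE)
  if (identical(name, "WT")) return(empty)
  tokens <- strsplit(name, "/", fixed = TRUE)[[1]]
  if (length(tokens) == 0) stop("empty construct name")
  parsed <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([A-Z])([0-9]+)([A-Z])$", tok))[[1]]
    if (length(m) != 4)
      stop(sprintf("malformed mutation token '%s' in '%s'", tok, name))
    if (m[2] == m[4])
      stop(sprintf("token '%s': wild-type and new residue are identical",
                   tok))
    data.frame(wt = m[2], pos = as.integer(m[3]), new = m[4],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parsed)
}

#' Apply point mutations to a sequence
#'
#' Positions are interpreted in the reference coordinate system of the
#' construct names; `offset` maps them onto a subsequence (local index =
#' position - offset), so mutations can be applied directly to loop
#' fragments. Every spec must match the stated wild-type residue at its
#' position; mismatches abort with the expected and found residues. Specs
#' whose positions fall outside the (offset) sequence are an error unless
#' `skip_out_of_range = TRUE`, which is the convenient mode when applying a
#' full construct name to a single loop fragment.
#'
#' @param seq A [protein_sequence()] or plain character string.
#' @param specs Data frame from [parse_construct_name()] (columns `wt`,
#'   `pos`, `new`).
#' @param offset Integer offset of the subsequence (0 for full-length).
#' @param skip_out_of_range Silently skip specs outside the sequence.
#' @return Same type as `seq`, with substitutions applied (length
#'   preserved).
#' @examples
#' apply_mutations("SGGHINPTVTFSLCLLGREPWRKFP",
#'                 parse_construct_name("T85A"), offset = 77)
#' @export
apply_mutations <- function(seq, specs, offset = 0,
                            skip_out_of_range = FALSE) {
  is_ps <- inherits(seq, "protein_sequence")
  res <- if (is_ps) seq$residues else seq
  chars <- strsplit(res, "")[[1]]
  if (nrow(specs) > 0) {
    for (i in seq_len(nrow(specs))) {
      local <- specs$pos[i] - offset
      if (local < 1 || local > length(chars)) {
        if (skip_out_of_range) next
        stop(sprintf("position %d (local %d) out of range [1, %d]",
                     specs$pos[i], local, length(chars)))
      }
      if (chars[local] != specs$wt[i])
        stop(sprintf(
          "wild-type mismatch at position %d: expected %s, found %s",
          specs$pos[i], specs$wt[i], chars[local]))
      chars[local] <- specs$new[i]
    }
  }
  out <- paste(chars, collapse = "")
  if (is_ps) protein_sequence(seq$id, out) else out
}

#' Scan a sequence for NPA-box motifs
#'
#' Finds all Asn-Pro-X triplets (X in `x_set`, default A/T/S) and classes
#' them as canonical (`NPA`) or variant. The aquaglyceroporin studied here
#' carries a variant NPT first box whose Thr -> Ala mutation restores the
#' canonical motif.
#'
#' @param seq A [protein_sequence()] or character string.
#' @param x_set Allowed third residues.
#' @return Data frame with columns `start` (1-based position of the N),
#'   `triplet` and `canonical` (logical); zero rows if none found.
#' @examples
#' find_np_motifs("SGGHINPTVT")  # NPT at 6
#' @export
find_np_motifs <- function(seq, x_set = c("A", "T", "S")) {
  res <- if (inherits(seq, "protein_sequence")) seq$residues else seq
  pattern <- sprintf("NP[%s]", paste(x_set, collapse = ""))
  m <- gregexpr(pattern, res)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(), triplet = character(),
                      canonical = logical(), stringsAsFactors = FALSE))
  starts <- as.integer(m)
  triplets <- substring(res, starts, starts + 2)
  data.frame(start = starts, triplet = triplets,
             canonical = triplets == "NPA", stringsAsFactors = FALSE)
}

#' Packaged loop-fragment table of aquaporin constructs
#'
#' Loads the bundled table of wild-type and mutant DrAqp3b loop fragments
#' (loops A-E) together with the inferred full-length coordinate offsets of
#' each fragment (anchored at the named mutation positions H53, T85, H154,
#' Y182 and A217).
#'
#' @return A list with elements `fragments` (data frame: `construct`,
#'   `loop_A` ... `loop_E`) and `offsets` (named integer vector per loop).
#' @export
table2_constructs <- function() {
  frag_path <- system.file("extdata", "aqp3b_loop_fragments.tsv",
                           package = "aquaflux", mustWork = TRUE)
  off_path <- system.file("extdata", "aqp3b_loop_offsets.tsv",
                          package = "aquaflux", mustWork = TRUE)
  fragments <- read.delim(frag_path, stringsAsFactors = FALSE)
  off <- read.delim(off_path, stringsAsFactors = FALSE)
  offsets <- setNames(as.integer(off$offset), off$loop)
  list(fragments = fragments, offsets = offsets)
}

#' Verify that the packaged mutant fragments follow from the WT fragments
#'
#' For every non-WT construct, parses the construct name, applies the
#' mutations to the wild-type loop fragments (with the per-loop offsets)
#' and compares against the stored mutant fragments.
#'
#' @param fixtures Optional result of [table2_constructs()]; loaded from
#'   the package by default.
#' @return Data frame (`construct`, `loop`, `expected`, `derived`, `pass`)
#'   with attribute `all_pass`.
#' @export
verify_table2 <- function(fixtures = table2_constructs()) {
  frag <- fixtures$fragments
  offsets <- fixtures$offsets
  wt <- frag[frag$construct == "WT", , drop = FALSE]
  if (nrow(wt) != 1) stop("fixture must contain exactly one WT row")
  loops <- names(offsets)
  rows <- list()
  for (i in which(frag$construct != "WT")) {
    specs <- parse_construct_name(frag$construct[i])
    for (lp in loops) {
      col <- paste0("loop_", lp)
      derived <- apply_mutations(wt[[col]], specs, offset = offsets[[lp]],
                                 skip_out_of_range = TRUE)
      rows[[length(rows) + 1]] <-
        data.frame(construct = frag$construct[i], loop = lp,
                   expected = frag[[col]][i], derived = derived,
                   pass = identical(derived, frag[[col]][i]),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, all_pass = all(out$pass))
}

#' Read or write plain FASTA protein files
#'
#' Thin wrappers over Biostrings for single- or multi-record amino-acid
#' FASTA.
#'
#' @param path File path.
#' @return `read_fasta` returns a named list of [protein_sequence()]s.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i)
    protein_sequence(names(set)[i], as.character(set[[i]])))
  setNames(out, names(set))
}

#' @rdname read_fasta
#' @param seqs List of [protein_sequence()]s (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("writing FASTA requires the Biostrings package")
  if (is.character(seqs)) {
    set <- Biostrings::AAStringSet(seqs)
  } else {
    set <- Biostrings::AAStringSet(
      setNames(vapply(seqs, function(s) s$residues, character(1)),
               vapply(seqs, function(s) s$id, character(1))))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
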