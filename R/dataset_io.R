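#' Write a dataset to an extended-XYZ file
#'
#' One frame per sample: atom-count line; a comment line with `key=value`
#' tokens (`n_states`, `charge`, `blocks`, optional `provenance`); atom
#' lines `symbol x y z` (Bohr); then one `KEY= v1 v2 ...` line per present
#' property block. Arrays are serialized row-major (state/pair, then atom,
#' then xyz), pairs in lexicographic i < j order. All numbers are written
#' with 17 significant digits so a read/write round trip preserves values
#' to better than 1e-12 relative.
#'
#' @param ds a [dataset()].
#' @param path output file path (conventionally `.exxyz`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "ndn_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(sprintf("%.17g", as.numeric(x)), collapse = " ")
  for (smp in ds$samples) {
    g <- smp$geometry
    blocks <- c(
      if (!is.null(smp$energies)) "energies",
      if (!is.null(smp$forces)) "forces",
      if (!is.null(smp$nacs)) "nacs",
      if (!is.null(smp$smooth_nacs)) "smooth_nacs",
      if (!is.null(smp$permanent_dipoles)) "permanent_dipoles",
      if (!is.null(smp$transition_dipoles)) "transition_dipoles"
    )
    prov <- ds$metadata$provenance
    comment <- paste0(
      "n_states=", smp$state_space$n_states,
      " charge=", g$total_charge,
      " units=au",
      " blocks=", if (length(blocks)) paste(blocks, collapse = ",") else "none",
      if (!is.null(prov)) paste0(" provenance=\"", prov, "\"") else ""
    )
    writeLines(as.character(n_atoms(g)), con)
    writeLines(comment, con)
    sym <- z_to_symbol(g$atomic_numbers)
    for (a in seq_len(n_atoms(g))) {
      writeLines(paste(sym[a], fmt(g$positions[a, ])), con)
    }
    wr <- function(key, x) writeLines(paste0(key, "= ", fmt(aperm_flat(x))), con)
    if (!is.null(smp$energies)) wr("ENERGIES", smp$energies)
    if (!is.null(smp$forces)) wr("FORCES", smp$forces)
    if (!is.null(smp$nacs)) wr("NACS", smp$nacs)
    if (!is.null(smp$smooth_nacs)) wr("SMOOTH_NACS", smp$smooth_nacs)
    if (!is.null(smp$permanent_dipoles)) wr("PERM_DIPOLES", smp$permanent_dipoles)
    if (!is.null(smp$transition_dipoles)) wr("TRANS_DIPOLES", smp$transition_dipoles)
  }
  invisible(path)
}

## row-major flatten: last index fastest
aperm_flat <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(as.numeric(x))
  as.numeric(aperm(x, rev(seq_along(d))))
}

unflatten_rm <- function(v, d) {
  aperm(array(v, dim = rev(d)), rev(seq_along(d)))
}

#' Read a dataset from an extended-XYZ file
#'
#' Inverse of [write_dataset()]. Malformed frames raise an error naming
#' the frame index and offending field. Every loaded sample carrying both
#' `nacs` and `smooth_nacs` is checked against the smoothing identity.
#'
#' @param path file path.
#' @return a [dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  samples <- list()
  meta <- list()
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame <- frame + 1L
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na < 1)
      stop("frame ", frame, ": invalid atom count line '", lines[pos], "'")
    if (pos + 1L > length(lines)) stop("frame ", frame, ": missing comment line")
    hdr <- parse_kv_line(lines[pos + 1L], frame)
    s <- as.integer(hdr$n_states)
    if (is.na(s)) stop("frame ", frame, ": missing n_states in comment line")
    charge <- if (!is.null(hdr$charge)) as.integer(hdr$charge) else 0L
    if (!is.null(hdr$provenance)) meta$provenance <- hdr$provenance
    if (pos + 1L + na > length(lines))
      stop("frame ", frame, ": truncated atom block (expected ", na, " atoms)")
    at <- lines[pos + 1L + seq_len(na)]
    toks <- strsplit(trimws(at), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1)) != 4)
    if (length(bad))
      stop("frame ", frame, ": malformed atom line ", bad[1])
    sym <- vapply(toks, `[[`, character(1), 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("frame ", frame, ": non-numeric coordinates")
    pos <- pos + 2L + na
    props <- list()
    while (pos <= length(lines) &&
           grepl("^[A-Z_]+= ", lines[pos])) {
      key <- sub("=.*$", "", lines[pos])
      vals <- suppressWarnings(as.numeric(strsplit(
        trimws(sub("^[A-Z_]+= *", "", lines[pos])), "[[:space:]]+")[[1]]))
      if (anyNA(vals)) stop("frame ", frame, ": non-numeric values in ", key)
      props[[key]] <- vals
      pos <- pos + 1L
    }
    ss <- state_space(s)
    p <- n_pairs(ss)
    need <- function(key, len) {
      v <- props[[key]]
      if (is.null(v)) return(NULL)
      if (length(v) != len)
        stop("frame ", frame, ": field ", key, " has length ", length(v),
             ", expected ", len)
      v
    }
    smp <- tryCatch(
      multistate_sample(
        geometry(symbol_to_z(sym), xyz, charge), ss,
        energies = need("ENERGIES", s),
        forces = arr_rm(need("FORCES", s * na * 3), c(s, na, 3)),
        nacs = arr_rm(need("NACS", p * na * 3), c(p, na, 3)),
        smooth_nacs = arr_rm(need("SMOOTH_NACS", p * na * 3), c(p, na, 3)),
        permanent_dipoles = arr_rm_t(need("PERM_DIPOLES", s * 3), s),
        transition_dipoles = arr_rm_t(need("TRANS_DIPOLES", p * 3), p)
      ),
      error = function(e) stop("frame ", frame, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    samples[[frame]] <- smp
  }
  dataset(samples, meta)
}

arr_rm <- function(v, d) if (is.null(v)) NULL else unflatten_rm(v, d)
arr_rm_t <- function(v, nr) if (is.null(v)) NULL else matrix(v, nr, 3, byrow = TRUE)

parse_kv_line <- function(line, frame) {
  out <- list()
  ## quoted values first
  q <- gregexpr('([a-z_]+)="([^"]*)"', line)
  m <- regmatches(line, q)[[1]]
  for (tok in m) {
    key <- sub("=.*$", "", tok)
    out[[key]] <- sub('^[a-z_]+="', "", sub('"$', "", tok))
  }
  line <- gsub('[a-z_]+="[^"]*"', "", line)
  for (tok in strsplit(trimws(line), "[[:space:]]+")[[1]]) {
    if (!nzchar(tok)) next
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("frame ", frame, ": malformed comment token '", tok, "'")
    out[[kv[1]]] <- kv[2]
  }
  out
}

.default_aliases <- list(
  positions = c("positions", "coords", "coordinates", "R", "xyz"),
  atomic_numbers = c("atomic_numbers", "numbers", "Z", "species", "elements"),
  charge = c("charge", "total_charge"),
  energies = c("energies", "energy", "E"),
  forces = c("forces", "F"),
  nacs = c("nacs", "nac", "couplings", "C"),
  smooth_nacs = c("smooth_nacs", "smoothed_nacs"),
  permanent_dipoles = c("permanent_dipoles", "dipoles", "mu"),
  transition_dipoles = c("transition_dipoles", "tdm", "mu_ij")
)

#' Convert generic per-frame records into a dataset
#'
#' Accepts a list of per-frame property mappings (named lists) in declared
#' units, resolves property names through a user-extensible alias table,
#' converts everything to atomic units, and optionally adds the smoothed
#' NAC block from raw NACs and energies.
#'
#' @param records list of named lists; each must supply coordinates and
#'   element numbers plus any property blocks.
#' @param units named list of unit declarations, e.g. `list(energy = "eV",
#'   position = "Angstrom", force = "eV/Angstrom")`. Omitted entries
#'   default to atomic units.
#' @param n_states number of electronic states.
#' @param aliases alias table; entries extend/override the built-in one.
#' @param smooth_nacs if `TRUE`, compute and store smoothed NACs when raw
#'   NACs and energies are present.
#' @param provenance free-text provenance stored in the metadata.
#' @return a [dataset()] in atomic units.
#' @export
convert_external_table <- function(records, units = list(), n_states,
                                   aliases = list(), smooth_nacs = FALSE,
                                   provenance = "converted") {
  al <- .default_aliases
  for (nm in names(aliases)) al[[nm]] <- union(al[[nm]], aliases[[nm]])
  u <- function(q, def = "au") if (!is.null(units[[q]])) units[[q]] else def
  lookup <- function(rec, field) {
    hit <- intersect(al[[field]], names(rec))
    if (length(hit) == 0) return(NULL)
    rec[[hit[1]]]
  }
  known <- unlist(al, use.names = FALSE)
  ss <- state_space(n_states)
  p <- n_pairs(ss)
  samples <- vector("list", length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    unknown <- setdiff(names(rec), known)
    if (length(unknown)) {
      stop("record ", k, ": unknown property name(s) ",
           paste(unknown, collapse = ", "), "; accepted aliases: ",
           paste(known, collapse = ", "))
    }
    posx <- lookup(rec, "positions")
    z <- lookup(rec, "atomic_numbers")
    if (is.null(posx) || is.null(z))
      stop("record ", k, ": coordinates and element numbers are required")
    posx <- to_atomic_units(as.matrix(posx),
                            u("position", "bohr"), "length")
    ch <- lookup(rec, "charge"); if (is.null(ch)) ch <- 0L
    na <- length(z)
    en <- lookup(rec, "energies")
    if (!is.null(en)) {
      if (length(en) != n_states)
        stop("record ", k, ": inconsistent state count (",
             length(en), " energies, expected ", n_states, ")")
      en <- to_atomic_units(as.numeric(en), u("energy", "hartree"), "energy")
    }
    fo <- lookup(rec, "forces")
    if (!is.null(fo)) fo <- to_atomic_units(array(fo, c(n_states, na, 3)),
                                            u("force", "hartree/bohr"), "force")
    nc <- lookup(rec, "nacs")
    if (!is.null(nc)) nc <- to_atomic_units(array(nc, c(p, na, 3)),
                                            u("nac", "1/bohr"), "nac")
    sn <- lookup(rec, "smooth_nacs")
    if (!is.null(sn)) sn <- to_atomic_units(array(sn, c(p, na, 3)),
                                            u("smooth_nac", "hartree/bohr"),
                                            "smooth_nac")
    pd <- lookup(rec, "permanent_dipoles")
    if (!is.null(pd)) pd <- to_atomic_units(matrix(pd, n_states, 3),
                                            u("dipole", "au"), "dipole")
    td <- lookup(rec, "transition_dipoles")
    if (!is.null(td)) td <- to_atomic_units(matrix(td, p, 3),
                                            u("dipole", "au"), "dipole")
    if (smooth_nacs && is.null(sn) && !is.null(nc) && !is.null(en)) {
      sn <- smooth_nacs_op(nc, en, ss)
    }
    samples[[k]] <- multistate_sample(
      geometry(z, posx, ch), ss, energies = en, forces = fo, nacs = nc,
      smooth_nacs = sn, permanent_dipoles = pd, transition_dipoles = td)
  }
  dataset(samples, list(provenance = provenance))
}
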