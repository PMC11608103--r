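#' Parse a geochemical constants database
#'
#' Reads the line-oriented, CrunchFlow-style constants database used by the
#' reaction-network builder. The dialect (full grammar in the README):
#'
#' ```
#' # comment
#' reaction "<signature>"  log10_keq = <num>  [log10_k = <num>]  [ssa = <num>]
#' ```
#'
#' Each entry keys a reaction signature (see [parse_reaction()]) to its log10
#' equilibrium constant and optional default kinetic constants. Signatures are
#' canonicalized (term order does not matter); duplicate signatures and unknown
#' keys are rejected.
#'
#' @param text Database text (single string or character vector of lines).
#' @return An object of class `rt_database`: a named list of entries keyed by
#'   canonical signature, each with `stoich`, `reversible`, `log10_keq`,
#'   `log10_k`, `ssa`.
#' @export
parse_database <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  lines <- text
  if (!length(lines) || all(grepl("^\\s*(#|$)", lines)))
    stopf("empty database text")
  entries <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (line == "") next
    m <- regmatches(line, regexec('^reaction\\s+"([^"]+)"\\s*(.*)$', line))[[1]]
    if (length(m) != 3)
      stopf("database line %d: cannot parse '%s' (expected: reaction \"<sig>\" key = value ...)",
            i, lines[i])
    parsed <- parse_reaction(m[2])
    sig <- reaction_signature(parsed$stoich, parsed$reversible)
    if (sig %in% names(entries))
      stopf("database line %d: duplicate reaction signature '%s'", i, sig)
    entry <- list(stoich = parsed$stoich, reversible = parsed$reversible,
                  log10_keq = NULL, log10_k = NULL, ssa = NULL)
    rest <- trimws(m[3])
    if (rest != "") {
      kvs <- strsplit(rest, "\\s+(?=[a-z_0-9]+\\s*=)", perl = TRUE)[[1]]
      for (kv in kvs) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        if (length(p) != 2)
          stopf("database line %d: malformed key-value '%s'", i, kv)
        key <- trimws(p[1]); val <- suppressWarnings(as.numeric(trimws(p[2])))
        if (!key %in% c("log10_keq", "log10_k", "ssa"))
          stopf("database line %d: unknown key '%s'", i, key)
        if (is.na(val)) stopf("database line %d: non-numeric value for '%s'",
                              i, key)
        entry[[key]] <- val
      }
    }
    if (is.null(entry$log10_keq))
      stopf("database line %d: entry '%s' lacks log10_keq", i, sig)
    entries[[sig]] <- entry
  }
  structure(entries, class = "rt_database")
}

#' Serialize a geochemical database
#'
#' Inverse of [parse_database()]: `parse_database(serialize_database(db))` is
#' identical to `db`.
#'
#' @param db An `rt_database`.
#' @return A single string of database text.
#' @export
serialize_database <- function(db) {
  stopifnot(inherits(db, "rt_database"))
  lines <- vapply(names(db), function(sig) {
    e <- db[[sig]]
    kv <- sprintf("log10_keq = %s", fmt_num(e$log10_keq))
    if (!is.null(e$log10_k)) kv <- paste(kv, sprintf("log10_k = %s", fmt_num(e$log10_k)))
    if (!is.null(e$ssa)) kv <- paste(kv, sprintf("ssa = %s", fmt_num(e$ssa)))
    sprintf('reaction "%s"  %s', sig, kv)
  }, character(1))
  paste(lines, collapse = "\n")
}

#' Look up a reaction signature in a database
#'
#' @param db An `rt_database`.
#' @param reaction Reaction signature string (canonicalized before lookup).
#' @return The entry list, or `NULL` if absent.
#' @export
db_lookup <- function(db, reaction) {
  parsed <- parse_reaction(reaction)
  sig <- reaction_signature(parsed$stoich, parsed$reversible)
  # equilibrium lookups are direction-insensitive for reversible reactions
  if (sig %in% names(db)) return(db[[sig]])
  if (parsed$reversible) {
    rsig <- reaction_signature(-parsed$stoich, TRUE)
    if (rsig %in% names(db)) {
      e <- db[[rsig]]
      e$log10_keq <- -e$log10_keq
      e$stoich <- -e$stoich
      return(e)
    }
  }
  NULL
}

#' Default geochemical database
#'
#' The constants shipped with the package: carbonate speciation (first and
#' second dissociation), water dissociation, DOC sorption, carbonate mineral
#' dissolution (shallow and deep stoichiometries) and the CO2 gas-aqueous
#' exchange reaction.
#'
#' @return An `rt_database`.
#' @export
default_database <- function() {
  parse_database(default_database_text())
}

default_database_text <- function() {
  paste(
    '# catchrt default constants database (CrunchFlow-style dialect)',
    '# carbonate system',
    'reaction "CO2(aq) + H2O = H+ + HCO3-"  log10_keq = -6.35',
    'reaction "HCO3- = CO3-- + H+"  log10_keq = -10.33',
    'reaction "H2O = H+ + OH-"  log10_keq = -14',
    '# DOC sorption on soil sites',
    'reaction "DOC + X = XDOC"  log10_keq = -1',
    '# carbonate mineral dissolution (zone-specific stoichiometries)',
    'reaction "Carbonate_SZ(s) -> 1.1 Ca++ + 0.5 HCO3-"  log10_keq = -7.4  log10_k = -9.19  ssa = 1',
    'reaction "Carbonate_DZ(s) -> 0.9 Ca++ + 0.7 HCO3-"  log10_keq = -7.4  log10_k = -9.19  ssa = 0.0008',
    '# soil CO2 gas-aqueous exchange',
    'reaction "CO2(*g) = CO2(aq)"  log10_keq = -3.2  log10_k = -13.1',
    sep = "\n")
}
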