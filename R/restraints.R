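# Restraint parsing and compilation.
#
# All restraint inputs -- dot-bracket secondary structure (multi-line for
# pseudoknots, 'x' to exclude residues from Watson-Crick pairing),
# noncanonical pair records in Leontis-Westhof notation, explicit distance
# restraints, and chemical-probing reactivity profiles -- compile into a
# `cg_restraints` set: a table of slope (hard penalty) or well (soft bonus)
# atom-atom distance restraints, an excluded-residue set and a reactivity
# vector.

DB_CHARS <- c(".", "(", ")", "x")

seq_chains <- function(sequence) {
  if (length(sequence) == 1 && is.null(names(sequence)) &&
      grepl(" ", sequence)) sequence <- strsplit(sequence, " +")[[1]]
  if (is.null(names(sequence))) names(sequence) <- LETTERS[seq_along(sequence)]
  sequence
}

seq_global_index <- function(sequence, chain, res) {
  sequence <- seq_chains(sequence)
  ci <- match(chain, names(sequence))
  if (any(is.na(ci))) stop("unknown chain ", chain[is.na(ci)][1], call. = FALSE)
  off <- c(0, cumsum(nchar(sequence)))[ci]
  bad <- res < 1 | res > nchar(sequence)[ci]
  if (any(bad))
    stop("residue ", chain[bad][1], "/", res[bad][1], " outside the sequence",
         call. = FALSE)
  off + res
}

seq_types <- function(sequence) {
  sequence <- seq_chains(sequence)
  strsplit(paste(sequence, collapse = ""), "")[[1]]
}

#' Parse dot-bracket secondary-structure restraints
#'
#' Each line spans the full (concatenated) sequence.  Matched `()` within a
#' line are nested; pseudoknots are expressed as additional lines whose
#' pairs may cross those of other lines.  `x` marks a residue excluded from
#' canonical (Watson-Crick-edge) pairing.
#'
#' @param lines character vector of dot-bracket lines over
#'   `{. ( ) x}`.
#' @param sequence sequence string(s): a single string, a space-separated
#'   multi-chain string, or a named character vector of chains.
#' @return an object of class `ss_spec`: list with `lines`, `pairs`
#'   (tibble `i`, `j`, `line`, global 1-based indices, `i < j`) and
#'   `excluded` (integer global indices).
#' @export
#' @examples
#' parse_dotbracket("((..))", "GGAACC")
parse_dotbracket <- function(lines, sequence) {
  types <- seq_types(sequence)
  n <- length(types)
  pairs <- list()
  excluded <- integer()
  for (li in seq_along(lines)) {
    ch <- strsplit(lines[li], "")[[1]]
    if (length(ch) != n)
      stop("dot-bracket line ", li, " has length ", length(ch),
           " but the sequence has ", n, " residues", call. = FALSE)
    bad <- which(!ch %in% DB_CHARS)
    if (length(bad))
      stop("dot-bracket line ", li, ": invalid character '", ch[bad[1]],
           "' at position ", bad[1], call. = FALSE)
    stack <- integer()
    for (p in seq_len(n)) {
      if (ch[p] == "(") {
        stack <- c(stack, p)
      } else if (ch[p] == ")") {
        if (!length(stack))
          stop("dot-bracket line ", li, ": unbalanced ')' at position ", p,
               call. = FALSE)
        i <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pairs[[length(pairs) + 1L]] <- c(i, p, li)
      }
    }
    if (length(stack))
      stop("dot-bracket line ", li, ": unbalanced '(' at position ",
           stack[length(stack)], call. = FALSE)
    excluded <- union(excluded, which(ch == "x"))
  }
  pairs <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    tibble::tibble(i = m[, 1], j = m[, 2], line = m[, 3])
  } else tibble::tibble(i = integer(), j = integer(), line = integer())
  hit <- intersect(excluded, c(pairs$i, pairs$j))
  if (length(hit))
    stop("position ", hit[1], " is marked 'x' in one line but paired in ",
         "another", call. = FALSE)
  structure(list(lines = lines, pairs = pairs,
                 excluded = sort(excluded), n = n),
            class = "ss_spec")
}

#' @rdname parse_dotbracket
#' @param spec an `ss_spec`.
#' @return `format_dotbracket()`: the dot-bracket lines.
#' @export
format_dotbracket <- function(spec) spec$lines

#' Parse noncanonical base-pair restraint records
#'
#' One record per line:
#' `chain i;residue i;type i;chain j;residue j;type j;pair type`, the pair
#' type being two Leontis-Westhof edge letters (`W`, `H`, `S`) followed by
#' the glycosidic orientation (`c` = cis, `t` = trans).  `A;8;A;A;21;G;HSt`
#' restrains A8 (adenine) to pair with A21 (guanine) on its Hoogsteen edge
#' against the guanine sugar edge, trans.  Lines starting with `#` and blank
#' lines are ignored.
#'
#' @param lines character vector of records.
#' @param sequence as in [parse_dotbracket()]; residue types are
#'   cross-checked against it.
#' @return tibble with columns `chain_i`, `res_i`, `type_i`, `chain_j`,
#'   `res_j`, `type_j`, `edge_i`, `edge_j`, `orientation`.
#' @export
parse_noncanonical <- function(lines, sequence) {
  sequence <- seq_chains(sequence)
  types <- seq_types(sequence)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(line) {
    f <- strsplit(line, ";", fixed = TRUE)[[1]]
    if (length(f) != 7)
      stop("noncanonical record '", line, "' must have 7 ';'-separated ",
           "fields", call. = FALSE)
    tok <- f[7]
    if (!grepl("^[WHS][WHS][ct]$", tok))
      stop("pair type '", tok, "' must be two edge letters (W/H/S) plus ",
           "orientation (c/t)", call. = FALSE)
    for (side in c(1, 4)) {
      gi <- seq_global_index(sequence, f[side], as.integer(f[side + 1]))
      if (types[gi] != f[side + 2])
        stop("record '", line, "': residue ", f[side], "/", f[side + 1],
             " is ", types[gi], " in the sequence, not ", f[side + 2],
             call. = FALSE)
    }
    tibble::tibble(chain_i = f[1], res_i = as.integer(f[2]), type_i = f[3],
                   chain_j = f[4], res_j = as.integer(f[5]), type_j = f[6],
                   edge_i = substr(tok, 1, 1), edge_j = substr(tok, 2, 2),
                   orientation = if (substr(tok, 3, 3) == "c") "cis" else "trans")
  })
  dplyr::bind_rows(rows)
}

#' @rdname parse_noncanonical
#' @param pairs tibble as returned by `parse_noncanonical()`.
#' @return `format_noncanonical()`: one record line per pair.
#' @export
format_noncanonical <- function(pairs) {
  sprintf("%s;%d;%s;%s;%d;%s;%s%s%s",
          pairs$chain_i, pairs$res_i, pairs$type_i,
          pairs$chain_j, pairs$res_j, pairs$type_j,
          pairs$edge_i, pairs$edge_j,
          ifelse(pairs$orientation == "cis", "c", "t"))
}

#' Compile one base-pair restraint into three distance restraints
#'
#' A base-pair restraint is enforced through three atom-atom distance
#' restraints between the three base beads of each partner (glycosidic
#' N-N, C2-C2, C6|C4-C6|C4), which pin both the distance and the mutual
#' orientation of the bases.  Targets come from the idealized family
#' geometry ([pair_targets()]); hard mode emits slope penalties, soft mode
#' well bonuses.
#'
#' @param pair one-row tibble as produced by [parse_noncanonical()] (or a
#'   list with the same fields).
#' @param mode `"hard"` (slope) or `"soft"` (well).
#' @param tol half-width of the satisfied window around each target
#'   distance (Angstrom).
#' @param weight slope steepness (energy per Angstrom) or well depth
#'   (energy) per distance restraint.
#' @return tibble of three distance restraints with columns `chain_a`,
#'   `res_a`, `bead_a`, `chain_b`, `res_b`, `bead_b`, `d_min`, `d_max`,
#'   `weight`, `form`.
#' @export
compile_pair <- function(pair, mode = c("hard", "soft"), tol = 0.5,
                         weight = 1) {
  mode <- match.arg(mode)
  tg <- tryCatch(
    pair_targets(pair$type_i, pair$type_j, pair$edge_i, pair$edge_j,
                 pair$orientation),
    error = function(e) stop(
      "no geometry for family ", pair$type_i, "-", pair$type_j, " ",
      pair$edge_i, pair$edge_j, " ", pair$orientation,
      "; supported edges are W, H, S with cis/trans orientation for all ",
      "base combinations", call. = FALSE))
  beads_a <- bead_names(pair$type_i)[3:5]
  beads_b <- bead_names(pair$type_j)[3:5]
  tibble::tibble(chain_a = pair$chain_i, res_a = pair$res_i, bead_a = beads_a,
                 chain_b = pair$chain_j, res_b = pair$res_j, bead_b = beads_b,
                 d_min = as.numeric(tg) - tol, d_max = as.numeric(tg) + tol,
                 weight = weight,
                 form = if (mode == "hard") "slope" else "well")
}

#' Compile dot-bracket secondary structure into distance restraints
#'
#' Every pair is compiled as a canonical cis Watson-Crick/Watson-Crick pair
#' via [compile_pair()].  In hard mode a residue may appear in at most one
#' pair across all lines; in soft mode mutually exclusive lines are allowed
#' and every alternative earns its own well bonus.
#'
#' @param spec an `ss_spec` from [parse_dotbracket()].
#' @param mode `"hard"` or `"soft"`.
#' @param sequence as in [parse_dotbracket()].
#' @inheritParams compile_pair
#' @return a `cg_restraints` set (distance table plus the spec's excluded
#'   residues).
#' @export
compile_secondary_structure <- function(spec, mode = c("hard", "soft"),
                                        sequence, tol = 0.5, weight = 1) {
  mode <- match.arg(mode)
  sequence <- seq_chains(sequence)
  types <- seq_types(sequence)
  if (mode == "hard" && nrow(spec$pairs)) {
    cnt <- table(c(spec$pairs$i, spec$pairs$j))
    dup <- names(cnt)[cnt > 1]
    if (length(dup))
      stop("hard restraints assign residue ", dup[1], " to several ",
           "partners, which would pull all of them together at once; ",
           "use soft mode for alternative pairings", call. = FALSE)
  }
  if (!nrow(spec$pairs))
    return(restraint_set(excluded = spec$excluded))
  addr <- global_to_chain(sequence)
  dist <- dplyr::bind_rows(lapply(seq_len(nrow(spec$pairs)), function(k) {
    i <- spec$pairs$i[k]; j <- spec$pairs$j[k]
    compile_pair(list(chain_i = addr$chain[i], res_i = addr$res[i],
                      type_i = types[i],
                      chain_j = addr$chain[j], res_j = addr$res[j],
                      type_j = types[j],
                      edge_i = "W", edge_j = "W", orientation = "cis"),
                 mode = mode, tol = tol, weight = weight)
  }))
  restraint_set(distance = dist, excluded = spec$excluded)
}

global_to_chain <- function(sequence) {
  sequence <- seq_chains(sequence)
  lens <- nchar(sequence)
  list(chain = rep(names(sequence), lens),
       res = unlist(lapply(lens, seq_len), use.names = FALSE))
}

#' Restraint energies of a single distance restraint
#'
#' Slope restraints penalize distances outside `[d_min, d_max]` linearly
#' (weight x violation, always >= 0).  Well restraints grant a flat bonus
#' `-weight` inside the window and are silent outside (always <= 0).
#'
#' @param d distance(s) in Angstrom.
#' @param r a one-row distance-restraint table (or list) with `d_min`,
#'   `d_max`, `weight` and `form`.
#' @return energy, vectorized over `d`.
#' @export
slope_energy <- function(d, r) {
  stopifnot(r$form == "slope")
  r$weight * pmax(0, pmax(r$d_min - d, d - r$d_max))
}

#' @rdname slope_energy
#' @export
well_energy <- function(d, r) {
  stopifnot(r$form == "well")
  -r$weight * as.numeric(d >= r$d_min & d <= r$d_max)
}

#' Parse a chemical-probing reactivity profile
#'
#' Comma-separated per-residue reactivities; chains separated by spaces;
#' `NA` marks an unassigned residue.  Values are clamped into [0, 1]
#' (below 0 becomes 0, above 1 becomes 1).
#'
#' @param text a single string (or character vector of per-chain strings).
#' @param sequence as in [parse_dotbracket()]; per-chain value counts must
#'   match chain lengths.
#' @return numeric vector over all residues (global order), `NA` where
#'   unassigned, with attribute `chains` giving the per-chain split.
#' @export
#' @examples
#' parse_reactivities("-0.2,0.5,1.3", "GCA")
parse_reactivities <- function(text, sequence) {
  sequence <- seq_chains(sequence)
  parts <- if (length(text) > 1) text else strsplit(trimws(text), " +")[[1]]
  if (length(parts) != length(sequence))
    stop("reactivities give ", length(parts), " chain(s) but the sequence ",
         "has ", length(sequence), call. = FALSE)
  vals <- lapply(seq_along(parts), function(ci) {
    tok <- trimws(strsplit(parts[ci], ",", fixed = TRUE)[[1]])
    if (length(tok) != nchar(sequence[ci]))
      stop("chain ", names(sequence)[ci], ": ", length(tok),
           " reactivities for ", nchar(sequence[ci]), " residues",
           call. = FALSE)
    v <- suppressWarnings(as.numeric(ifelse(tok == "NA", NA, tok)))
    if (any(is.na(v) & tok != "NA"))
      stop("chain ", names(sequence)[ci], ": non-numeric reactivity '",
           tok[which(is.na(v) & tok != "NA")[1]], "'", call. = FALSE)
    pmin(1, pmax(0, v))
  })
  out <- unlist(vals, use.names = FALSE)
  attr(out, "chains") <- lengths(vals)
  out
}

#' @rdname parse_reactivities
#' @param values reactivity vector (optionally with a `chains` attribute).
#' @return `format_reactivities()`: the text form.
#' @export
format_reactivities <- function(values) {
  chains <- attr(values, "chains")
  if (is.null(chains)) chains <- length(values)
  split_idx <- rep(seq_along(chains), chains)
  paste(vapply(split(as.numeric(values), split_idx), function(v) {
    paste(ifelse(is.na(v), "NA", sprintf("%.15g", v)), collapse = ",")
  }, character(1)), collapse = " ")
}

#' Chemical-probing restraint score
#'
#' Squared error between the current pairing pattern (0 = residue in a
#' canonical pair, 1 = unpaired) and the provided reactivities; residues
#' without an assigned reactivity are skipped.
#'
#' @param paired_flags per-residue 0/1 vector (0 = paired).
#' @param profile reactivity vector in [0, 1] with `NA` for unassigned.
#' @return non-negative score.
#' @export
probing_score <- function(paired_flags, profile) {
  stopifnot(length(paired_flags) == length(profile))
  ok <- !is.na(profile)
  sum((paired_flags[ok] - profile[ok])^2)
}

#' Restraint set container
#'
#' @param distance tibble of distance restraints (see [compile_pair()]).
#' @param excluded integer global residue indices barred from
#'   Watson-Crick-edge pairing.
#' @param reactivity reactivity vector (see [parse_reactivities()]), or
#'   `NULL`.
#' @return object of class `cg_restraints`.
#' @export
restraint_set <- function(distance = NULL, excluded = integer(),
                          reactivity = NULL) {
  if (is.null(distance))
    distance <- tibble::tibble(chain_a = character(), res_a = integer(),
                               bead_a = character(), chain_b = character(),
                               res_b = integer(), bead_b = character(),
                               d_min = numeric(), d_max = numeric(),
                               weight = numeric(), form = character())
  stopifnot(all(distance$d_min < distance$d_max), all(distance$weight > 0))
  structure(list(distance = tibble::as_tibble(distance),
                 excluded = as.integer(excluded),
                 reactivity = reactivity),
            class = "cg_restraints")
}

#' @export
print.cg_restraints <- function(x, ...) {
  cat("<cg_restraints> ", sum(x$distance$form == "slope"), " slope + ",
      sum(x$distance$form == "well"), " well restraints, ",
      length(x$excluded), " excluded residue(s), ",
      if (is.null(x$reactivity)) "no" else sum(!is.na(x$reactivity)),
      " probing value(s)\n", sep = "")
  invisible(x)
}

#' Merge restraint sets
#'
#' @param ... `cg_restraints` objects.
#' @return the combined set (reactivity may be supplied by at most one).
#' @export
merge_restraints <- function(...) {
  sets <- list(...)
  react <- Filter(Negate(is.null), lapply(sets, `[[`, "reactivity"))
  if (length(react) > 1)
    stop("at most one restraint set may carry a reactivity profile",
         call. = FALSE)
  restraint_set(
    distance = dplyr::bind_rows(lapply(sets, `[[`, "distance")),
    excluded = sort(unique(unlist(lapply(sets, `[[`, "excluded")))),
    reactivity = if (length(react)) react[[1]] else NULL)
}

#' Parse explicit pairwise distance restraints
#'
#' Line format: `SLOPE chain/res/bead chain/res/bead d_min d_max weight`
#' (or `WELL ...`), e.g. `SLOPE A/8/N9 A/21/N9 8.5 9.5 1.0`.
#'
#' @param lines character vector; `#` comments and blank lines ignored.
#' @return tibble in the [compile_pair()] distance-restraint layout.
#' @export
parse_distance_restraints <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(line) {
    f <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(f) != 6 || !toupper(f[1]) %in% c("SLOPE", "WELL"))
      stop("bad distance restraint line: '", line, "'", call. = FALSE)
    a <- strsplit(f[2], "/", fixed = TRUE)[[1]]
    b <- strsplit(f[3], "/", fixed = TRUE)[[1]]
    if (length(a) != 3 || length(b) != 3)
      stop("atom address must be chain/residue/bead: '", line, "'",
           call. = FALSE)
    tibble::tibble(chain_a = a[1], res_a = as.integer(a[2]), bead_a = a[3],
                   chain_b = b[1], res_b = as.integer(b[2]), bead_b = b[3],
                   d_min = as.numeric(f[4]), d_max = as.numeric(f[5]),
                   weight = as.numeric(f[6]),
                   form = tolower(f[1]))
  })
  dplyr::bind_rows(rows)
}

#' @rdname parse_distance_restraints
#' @param distance distance-restraint tibble.
#' @return `format_distance_restraints()`: one line per restraint.
#' @export
format_distance_restraints <- function(distance) {
  sprintf("%s %s/%d/%s %s/%d/%s %.6g %.6g %.6g",
          toupper(distance$form),
          distance$chain_a, distance$res_a, distance$bead_a,
          distance$chain_b, distance$res_b, distance$bead_b,
          distance$d_min, distance$d_max, distance$weight)
}
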