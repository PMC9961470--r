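AGP_COLUMNS <- c("object_id", "object_beg", "object_end", "part_number",
                 "component_type", "component_id", "component_beg",
                 "component_end", "orientation", "gap_length", "gap_type",
                 "linkage", "evidence")

agp_skeleton <- function(n = 0L) {
  data.frame(
    object_id      = character(n),
    object_beg     = integer(n),
    object_end     = integer(n),
    part_number    = integer(n),
    component_type = character(n),
    component_id   = NA_character_,
    component_beg  = NA_integer_,
    component_end  = NA_integer_,
    orientation    = NA_character_,
    gap_length     = NA_integer_,
    gap_type       = NA_character_,
    linkage        = NA_character_,
    evidence       = NA_character_,
    stringsAsFactors = FALSE
  )[seq_len(n), , drop = FALSE]
}

#' Validate a set of AGP records
#'
#' Checks the structural invariants of AGP v2.x: `object_end >= object_beg`;
#' for `W` components the object span equals the component span; part
#' numbers within an object are consecutive from 1; adjacent parts tile the
#' object without gaps or overlaps.
#'
#' @param agp data.frame of AGP records (see [read_agp()] for the columns).
#' @return `agp`, invisibly, or an error describing the first violation.
#' @export
validate_agp <- function(agp) {
  required <- c("object_id", "object_beg", "object_end", "part_number",
                "component_type")
  miss <- setdiff(required, names(agp))
  if (length(miss)) abort("AGP records missing columns: ",
                          paste(miss, collapse = ", "))
  if (nrow(agp) == 0L) return(invisible(agp))
  bad_type <- !agp$component_type %in% c("W", "U", "N")
  if (any(bad_type)) {
    abort("unknown component_type: ", agp$component_type[bad_type][1L])
  }
  if (any(agp$object_end < agp$object_beg)) {
    abort("object_end < object_beg in AGP record")
  }
  w <- agp$component_type == "W"
  if (any(w)) {
    span_obj <- agp$object_end[w] - agp$object_beg[w]
    span_cmp <- agp$component_end[w] - agp$component_beg[w]
    if (anyNA(span_cmp)) abort("W record missing component coordinates")
    if (any(span_obj != span_cmp)) {
      bad <- agp$component_id[w][which(span_obj != span_cmp)[1L]]
      abort("W span mismatch between object and component for ", bad)
    }
    if (any(!agp$orientation[w] %in% c("+", "-"))) {
      abort("W record orientation must be '+' or '-'")
    }
  }
  for (obj in unique(agp$object_id)) {
    rows <- agp[agp$object_id == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    if (!identical(as.integer(rows$part_number), seq_len(nrow(rows)))) {
      abort("part_numbers not consecutive from 1 for object ", obj)
    }
    if (rows$object_beg[1L] != 1L) {
      abort("first part of object ", obj, " does not start at 1")
    }
    if (nrow(rows) > 1L) {
      gaps <- rows$object_beg[-1L] - rows$object_end[-nrow(rows)]
      if (any(gaps != 1L)) {
        abort("parts of object ", obj, " do not tile the object")
      }
    }
  }
  invisible(agp)
}

#' Read an AGP v2.x file
#'
#' @param path Path to a tab-separated AGP file; lines starting with `#`
#'   are comments.
#' @return data.frame with columns `object_id`, `object_beg`, `object_end`,
#'   `part_number`, `component_type`, and, depending on the component type,
#'   `component_id`/`component_beg`/`component_end`/`orientation` (type `W`)
#'   or `gap_length`/`gap_type`/`linkage`/`evidence` (type `U`/`N`).
#'   Coordinates are 1-based inclusive. Records are returned in file order
#'   and validated with [validate_agp()].
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  out <- agp_skeleton(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      abort("line ", lineno[i], ": AGP rows need 9 tab-separated columns")
    }
    coords <- suppressWarnings(as.integer(f[c(2, 3, 4)]))
    if (anyNA(coords)) {
      abort("line ", lineno[i], ": non-integer object coordinates")
    }
    out$object_id[i] <- f[1L]
    out$object_beg[i] <- coords[1L]
    out$object_end[i] <- coords[2L]
    out$part_number[i] <- coords[3L]
    out$component_type[i] <- f[5L]
    if (f[5L] == "W") {
      cmp <- suppressWarnings(as.integer(f[c(7, 8)]))
      if (anyNA(cmp)) {
        abort("line ", lineno[i], ": non-integer component coordinates")
      }
      out$component_id[i] <- f[6L]
      out$component_beg[i] <- cmp[1L]
      out$component_end[i] <- cmp[2L]
      out$orientation[i] <- f[9L]
    } else if (f[5L] %in% c("U", "N")) {
      gl <- suppressWarnings(as.integer(f[6L]))
      if (is.na(gl)) abort("line ", lineno[i], ": non-integer gap length")
      out$gap_length[i] <- gl
      out$gap_type[i] <- f[7L]
      out$linkage[i] <- f[8L]
      out$evidence[i] <- f[9L]
    } else {
      abort("line ", lineno[i], ": unknown component_type '", f[5L], "'")
    }
  }
  validate_agp(out)
  out
}

#' Write AGP v2.1
#'
#' Records are validated before anything is written, then emitted ordered
#' by `(object_id, part_number)` under an AGP 2.1 header. Output is
#' deterministic for identical input.
#'
#' @param agp data.frame of AGP records (columns as in [read_agp()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  header <- c("##agp-version\t2.1",
              paste0("# generated by ctga ",
                     as.character(utils::packageVersion("ctga"))))
  if (nrow(agp)) {
    agp <- agp[order(agp$object_id, agp$part_number), , drop = FALSE]
    w <- agp$component_type == "W"
    c6 <- ifelse(w, agp$component_id, as.character(agp$gap_length))
    c7 <- ifelse(w, as.character(agp$component_beg), agp$gap_type)
    c8 <- ifelse(w, as.character(agp$component_end), agp$linkage)
    c9 <- ifelse(w, agp$orientation, agp$evidence)
    body <- paste(agp$object_id, agp$object_beg, agp$object_end,
                  agp$part_number, agp$component_type, c6, c7, c8, c9,
                  sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
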