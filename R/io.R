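#' Read a metabolic network
#'
#' Plain-text format: one reaction per line,
#' `rid : coeff cid + coeff cid ... -> coeff cid + ...`, with `->` for an
#' irreversible and `<=>` for a reversible reaction; an omitted coefficient
#' means `1.0`; `#` starts a comment. SBML (level 2/3) is read with a
#' minimal namespace-agnostic parser: species become compounds, reactant /
#' product speciesReferences carry the stoichiometry, species flagged
#' `boundaryCondition="true"` are recorded in the `boundary` attribute.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"txt"` or `"sbml"`.
#' @param sources,targets character vectors of compound ids (or `NULL`).
#' @param autosources if `TRUE` and `sources` is `NULL`, take as sources all
#'   compounds that are produced by no reaction, or only by reversible
#'   reactions (the usual convention when a model does not declare an
#'   environment).
#' @param normalize normalize the network after reading (default).
#' @return a `metabolic_network`.
#' @export
read_network <- function(path, format = c("auto", "txt", "sbml"),
                         sources = NULL, targets = NULL,
                         autosources = FALSE, normalize = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "txt"
  }
  parsed <- if (format == "txt") .read_network_txt(path) else .read_sbml(path)
  reactions <- parsed$reactions
  if (autosources && is.null(sources)) {
    prod_irrev <- unique(unlist(lapply(reactions, function(r)
      if (!r$reversible) names(r$products))))
    all_cmp <- unique(unlist(lapply(reactions, function(r)
      c(names(r$substrates), names(r$products)))))
    sources <- setdiff(all_cmp, prod_irrev)
  }
  net <- metabolic_network(reactions,
                           sources = if (is.null(sources)) character(0) else sources,
                           targets = if (is.null(targets)) character(0) else targets,
                           compounds = parsed$compounds)
  attr(net, "boundary") <- parsed$boundary
  if (normalize) net <- normalize_network(net)
  net
}

.read_network_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  reactions <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 0) stop("line ", ln, ": missing 'id :' prefix")
    rid <- trimws(substr(line, 1, colon - 1))
    body <- trimws(substr(line, colon + 1, nchar(line)))
    rev <- grepl("<=>", body, fixed = TRUE)
    parts <- if (rev) strsplit(body, "<=>", fixed = TRUE)[[1]]
             else strsplit(body, "->", fixed = TRUE)[[1]]
    if (length(parts) > 2 || (!rev && !grepl("->", body, fixed = TRUE))) {
      stop("line ", ln, ": expected exactly one '->' or '<=>'")
    }
    if (length(parts) == 1) parts <- c(parts, "")
    side <- function(txt, which) {
      txt <- trimws(txt)
      if (!nzchar(txt)) return(numeric(0))
      terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
      out <- numeric(0)
      for (tm in terms) {
        if (!nzchar(tm)) stop("line ", ln, ": empty term on ", which, " side")
        tok <- strsplit(tm, "[[:space:]]+")[[1]]
        if (length(tok) == 1) {
          coeff <- 1
          cid <- tok
        } else if (length(tok) == 2) {
          coeff <- suppressWarnings(as.numeric(tok[1]))
          if (is.na(coeff)) stop("line ", ln, ": bad coefficient '", tok[1],
                                 "'")
          cid <- tok[2]
        } else {
          stop("line ", ln, ": cannot parse term '", tm, "'")
        }
        out[cid] <- coeff
      }
      out
    }
    reactions[[length(reactions) + 1L]] <-
      tryCatch(reaction(rid, side(parts[1], "substrate"),
                        side(parts[2], "product"), reversible = rev),
               error = function(e) stop("line ", ln, ": ",
                                        conditionMessage(e), call. = FALSE))
  }
  list(reactions = reactions, compounds = NULL, boundary = character(0))
}

.read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  boundary <- sp_ids[!is.na(xml2::xml_attr(sp_nodes, "boundaryCondition")) &
                       xml2::xml_attr(sp_nodes, "boundaryCondition") == "true"]
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  reactions <- list()
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    pick <- function(tag) {
      refs <- xml2::xml_find_all(
        rx, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']",
                    tag))
      if (!length(refs)) return(numeric(0))
      sp <- xml2::xml_attr(refs, "species")
      st <- xml2::xml_attr(refs, "stoichiometry")
      if (anyNA(st)) {
        stop("SBML reaction '", rid,
             "': speciesReference without stoichiometry")
      }
      stats::setNames(as.numeric(st), sp)
    }
    reactions[[length(reactions) + 1L]] <-
      reaction(rid, pick("listOfReactants"), pick("listOfProducts"),
               reversible = rev)
  }
  list(reactions = reactions, compounds = sp_ids, boundary = boundary)
}

#' Write a network in the plain-text reaction-list format
#'
#' @param net a `metabolic_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  side <- function(s) paste(sprintf("%.10g %s", unname(s), names(s)),
                            collapse = " + ")
  lines <- vapply(net$reactions, function(r) {
    sprintf("%s: %s %s %s", r$id, side(r$substrates),
            if (r$reversible) "<=>" else "->", side(r$products))
  }, "")
  writeLines(trimws(lines), path)
  invisible(path)
}

#' Read a compound list (one id per line, `#` comments)
#' @param path file to read.
#' @return character vector.
#' @export
read_compound_list <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines[nzchar(lines)]
}

# ---- result serialisation ------------------------------------------------

.result_json <- function(res) {
  list(mode = res$mode,
       method = res$method,
       config = unclass(res$config),
       iterations = res$iterations,
       terminated_reason = res$terminated_reason,
       solutions = lapply(res$solutions, function(s) {
         out <- list(sources = as.list(s$sources),
                     support = as.list(s$support))
         if (!is.null(s$flux)) {
           fl <- s$flux[s$flux > 0]
           out$flux <- as.list(fl)
         }
         if (!is.null(s$found_at_k)) out$found_at_k <- s$found_at_k
         out
       }))
}

#' Write an enumeration result as JSON and TSV
#'
#' JSON is the authoritative output (solutions with flux certificates, the
#' configuration echo, and termination metadata); the TSV is a lossy
#' one-solution-per-row convenience view, byte-identical across runs for
#' identical inputs.
#'
#' @param res an `sps_enumeration`.
#' @param json_path,tsv_path output files (`NULL` to skip either).
#' @return invisible `NULL`.
#' @export
write_result <- function(res, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(.result_json(res), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    header <- "n_sources\tsources"
    rows <- vapply(res$solutions, function(s)
      sprintf("%d\t%s", length(s$sources), paste(s$sources, collapse = ",")),
      "")
    writeLines(c(header, rows), tsv_path)
  }
  invisible(NULL)
}

#' Assemble a run manifest
#'
#' Provenance record emitted alongside every CLI result: input paths and
#' their MD5 hashes, the full configuration echo, solver backend, wall time
#' and termination reason.
#'
#' @param inputs named character vector of input file paths.
#' @param config an [sps_config()].
#' @param res an `sps_enumeration`.
#' @param wall_time seconds.
#' @return a list (serialise with [jsonlite::write_json()]).
#' @export
run_manifest <- function(inputs, config, res, wall_time) {
  hashes <- vapply(inputs, function(p)
    unname(tools::md5sum(p)), "")
  list(inputs = as.list(inputs),
       md5 = as.list(hashes),
       config = unclass(config),
       mode = res$mode,
       method = res$method,
       backend = paste0("minprec internal simplex/branch-and-bound ",
                        as.character(utils::packageVersion("minprec"))),
       r_version = R.version.string,
       wall_time_s = wall_time,
       terminated_reason = res$terminated_reason)
}
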