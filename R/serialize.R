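# Serialization: N-Quads (canonical, line-sorted) and TriG (human-facing),
# plus a Turtle subset on read for fixture ontologies. The grammar is
# deliberately restricted: no blank nodes, no collections, no numeric/boolean
# shorthand literals — every term is an IRI, a CURIE or a quoted literal.

escape_nq <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_nq <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (!grepl("\\", s, fixed = TRUE)) { out[[i]] <- s; next }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        rep <- switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t",
          "\"" = "\"", "\\" = "\\",
          "u" = NA_character_, "U" = NA_character_, NULL)
        if (is.null(rep)) {
          np_error(sprintf("invalid escape '\\%s' in literal", nxt), "np_parse_error")
        }
        if (is.na(rep)) { # \uXXXX / \UXXXXXXXX
          width <- if (nxt == "u") 4L else 8L
          hex <- paste(chars[(j + 2L):(j + 1L + width)], collapse = "")
          rep <- intToUtf8(strtoi(hex, 16L))
          j <- j + width
        }
        buf <- c(buf, rep)
        j <- j + 2L
      } else {
        buf <- c(buf, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

format_object_nq <- function(row) {
  if (row$o_type == "iri") return(paste0("<", row$o, ">"))
  lit <- paste0("\"", escape_nq(row$o), "\"")
  if (!is.na(row$o_lang)) return(paste0(lit, "@", row$o_lang))
  if (!is.na(row$o_dt)) return(paste0(lit, "^^<", row$o_dt, ">"))
  lit
}

quads_to_nq_lines <- function(quads) {
  if (nrow(quads) == 0) return(character(0))
  objs <- vapply(seq_len(nrow(quads)),
                 function(i) format_object_nq(quads[i, ]), character(1))
  lines <- paste0("<", quads$s, "> <", quads$p, "> ", objs, " <", quads$g, "> .")
  sort(unique(lines), method = "radix")
}

compact_term <- function(iri_str, prefixes) {
  # longest-prefix match; only compact when the local part is PN_LOCAL-safe
  if (length(prefixes) == 0) return(paste0("<", iri_str, ">"))
  ns <- unname(prefixes)
  hit <- which(startsWith(iri_str, ns))
  if (length(hit) == 0) return(paste0("<", iri_str, ">"))
  hit <- hit[which.max(nchar(ns[hit]))]
  local <- substr(iri_str, nchar(ns[hit]) + 1L, nchar(iri_str))
  if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.:-]*$", local) && !endsWith(local, ".")) {
    paste0(names(prefixes)[hit], ":", local)
  } else {
    paste0("<", iri_str, ">")
  }
}

format_object_trig <- function(row, prefixes) {
  if (row$o_type == "iri") return(compact_term(row$o, prefixes))
  lit <- paste0("\"", escape_nq(row$o), "\"")
  if (!is.na(row$o_lang)) return(paste0(lit, "@", row$o_lang))
  if (!is.na(row$o_dt)) return(paste0(lit, "^^", compact_term(row$o_dt, prefixes)))
  lit
}

#' Serialize a graph bundle
#'
#' N-Quads output is line-sorted and duplicate-free, so two bundles are
#' set-equal exactly when their N-Quads renderings are byte-identical — this
#' is the canonical test serialization. TriG output groups statements by named
#' graph and compacts IRIs through the bundle's prefix map.
#'
#' @param bundle A [graph_bundle()].
#' @param dialect `"nquads"` or `"trig"`.
#' @return A single character string (the document).
#' @export
write_quads <- function(bundle, dialect = c("nquads", "trig")) {
  stopifnot(inherits(bundle, "graph_bundle"))
  dialect <- match.arg(dialect)
  quads <- bundle$quads
  if (dialect == "nquads") {
    lines <- quads_to_nq_lines(quads)
    return(if (length(lines) == 0) "" else paste0(paste(lines, collapse = "\n"), "\n"))
  }
  prefixes <- bundle$prefixes
  used <- function(iri_str) any(startsWith(iri_str, unname(prefixes)))
  out <- character(0)
  if (length(prefixes) > 0) {
    out <- c(out, paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> ."), "")
  }
  for (g in sort(unique(quads$g), method = "radix")) {
    gq <- quads[quads$g == g, , drop = FALSE]
    key <- paste(gq$s, gq$p, vapply(seq_len(nrow(gq)),
                 function(i) format_object_trig(gq[i, ], prefixes), character(1)))
    gq <- gq[order(key, method = "radix"), , drop = FALSE]
    out <- c(out, paste0(compact_term(g, prefixes), " {"))
    for (i in seq_len(nrow(gq))) {
      out <- c(out, paste0("    ",
                           compact_term(gq$s[i], prefixes), " ",
                           compact_term(gq$p[i], prefixes), " ",
                           format_object_trig(gq[i, ], prefixes), " ."))
    }
    out <- c(out, "}", "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---- N-Quads reader -------------------------------------------------------

parse_nq_line <- function(line, lineno) {
  pat <- paste0(
    "^\\s*<([^>]*)>\\s+<([^>]*)>\\s+",
    "(<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\"(?:@[A-Za-z0-9-]+|\\^\\^<[^>]*>)?)\\s+",
    "<([^>]*)>\\s+\\.\\s*$")
  m <- regmatches(line, regexec(pat, line, perl = TRUE))[[1]]
  if (length(m) == 0) {
    np_error(sprintf("N-Quads syntax error at line %d: %s", lineno, line),
             "np_parse_error")
  }
  s <- m[2]; p <- m[3]; obj <- m[4]; g <- m[5]
  if (startsWith(obj, "<")) {
    orow <- data.frame(o = substr(obj, 2, nchar(obj) - 1L), o_type = "iri",
                       o_dt = NA_character_, o_lang = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    lm <- regmatches(obj, regexec(
      "^\"((?:[^\"\\\\]|\\\\.)*)\"(?:@([A-Za-z0-9-]+)|\\^\\^<([^>]*)>)?$",
      obj, perl = TRUE))[[1]]
    orow <- data.frame(
      o = unescape_nq(lm[2]), o_type = "literal",
      o_dt = if (nzchar(lm[4])) lm[4] else NA_character_,
      o_lang = if (nzchar(lm[3])) lm[3] else NA_character_,
      stringsAsFactors = FALSE)
  }
  cbind(data.frame(s = s, p = p, stringsAsFactors = FALSE), orow,
        data.frame(g = g, stringsAsFactors = FALSE))
}

# ---- TriG / Turtle tokenizer ----------------------------------------------

tokenize_trig <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", 0L)
  i <- 1L; line <- 1L
  push <- function(type, value) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, line = line)
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[[i]] != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[[j]] != ">") {
        if (chars[[j]] == "\n") np_error(
          sprintf("unterminated IRI at line %d", line), "np_parse_error")
        j <- j + 1L
      }
      if (j > n) np_error(sprintf("unterminated IRI at line %d", line), "np_parse_error")
      push("iriref", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L; buf <- character(0)
      repeat {
        if (j > n) np_error(sprintf("unterminated string at line %d", line), "np_parse_error")
        cj <- chars[[j]]
        if (cj == "\\") { buf <- c(buf, cj, chars[[j + 1L]]); j <- j + 2L; next }
        if (cj == "\"") break
        if (cj == "\n") line <- line + 1L
        buf <- c(buf, cj); j <- j + 1L
      }
      push("string", unescape_nq(paste(buf, collapse = "")))
      i <- j + 1L; next
    }
    if (ch == "@") {
      j <- i + 1L
      while (j <= n && grepl("[A-Za-z0-9-]", chars[[j]])) j <- j + 1L
      word <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (word == "prefix") push("at_prefix", "@prefix") else push("langtag", word)
      i <- j; next
    }
    if (ch == "^" && i < n && chars[[i + 1L]] == "^") {
      push("dtmarker", "^^"); i <- i + 2L; next
    }
    if (ch %in% c("{", "}", ";", ",", ".")) {
      # '.' inside a PNAME is handled in the PNAME branch; bare '.' ends a stmt
      push(switch(ch, "{" = "lbrace", "}" = "rbrace",
                  ";" = "semicolon", "," = "comma", "." = "dot"), ch)
      i <- i + 1L; next
    }
    if (grepl("[A-Za-z0-9_]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_.:-]", chars[[j]])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      # a trailing '.' is the statement terminator, not part of the name
      ndots <- 0L
      while (endsWith(word, ".")) { word <- substr(word, 1, nchar(word) - 1L); ndots <- ndots + 1L }
      if (word == "a") {
        push("kw_a", "a")
      } else if (word %in% c("GRAPH", "graph")) {
        push("kw_graph", word)
      } else if (word %in% c("PREFIX", "prefix")) {
        push("at_prefix", word)
      } else if (grepl(":", word, fixed = TRUE)) {
        push("pname", word)
      } else {
        np_error(sprintf("unexpected token '%s' at line %d", word, line), "np_parse_error")
      }
      if (ndots > 0L) for (k in seq_len(ndots)) push("dot", ".")
      i <- i + nchar(word) + ndots; next
    }
    np_error(sprintf("unexpected character '%s' at line %d", ch, line), "np_parse_error")
  }
  toks
}

# Recursive-descent parser for the TriG subset (graphs + predicate/object
# lists) and Turtle (same grammar without graph blocks).
trig_parser <- function(tokens, dialect, default_graph) {
  pos <- 1L
  prefixes <- character(0)
  quads <- list()

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { t <- tokens[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) {
      np_error(sprintf("parse error at line %s: expected %s, got %s",
                       if (is.null(t)) "EOF" else t$line, type,
                       if (is.null(t)) "end of input" else t$type),
               "np_parse_error")
    }
    advance()
  }
  term_iri <- function(t) {
    if (t$type == "iriref") return(t$value)
    if (t$type == "pname") {
      return(as.character(resolve_curie(t$value, prefixes)))
    }
    np_error(sprintf("expected IRI at line %d, got %s", t$line, t$type),
             "np_parse_error")
  }
  parse_object <- function() {
    t <- advance()
    if (t$type %in% c("iriref", "pname")) {
      return(data.frame(o = term_iri(t), o_type = "iri",
                        o_dt = NA_character_, o_lang = NA_character_,
                        stringsAsFactors = FALSE))
    }
    if (t$type == "string") {
      nx <- peek()
      if (!is.null(nx) && nx$type == "langtag") {
        advance()
        return(data.frame(o = t$value, o_type = "literal",
                          o_dt = NA_character_, o_lang = nx$value,
                          stringsAsFactors = FALSE))
      }
      if (!is.null(nx) && nx$type == "dtmarker") {
        advance()
        dt <- term_iri(advance())
        return(data.frame(o = t$value, o_type = "literal",
                          o_dt = dt, o_lang = NA_character_,
                          stringsAsFactors = FALSE))
      }
      return(data.frame(o = t$value, o_type = "literal",
                        o_dt = NA_character_, o_lang = NA_character_,
                        stringsAsFactors = FALSE))
    }
    np_error(sprintf("expected object term at line %d", t$line), "np_parse_error")
  }
  parse_triples <- function(graph_iri) {
    s <- term_iri(advance())
    repeat {
      t <- advance()
      p <- if (t$type == "kw_a")
        "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" else term_iri(t)
      repeat {
        orow <- parse_object()
        quads[[length(quads) + 1L]] <<- cbind(
          data.frame(s = s, p = p, stringsAsFactors = FALSE), orow,
          data.frame(g = graph_iri, stringsAsFactors = FALSE))
        nx <- peek()
        if (!is.null(nx) && nx$type == "comma") { advance(); next }
        break
      }
      nx <- peek()
      if (!is.null(nx) && nx$type == "semicolon") {
        advance()
        nx2 <- peek()
        if (!is.null(nx2) && nx2$type %in% c("dot", "rbrace")) break
        next
      }
      break
    }
  }
  parse_graph_block <- function() {
    t <- peek()
    if (t$type == "kw_graph") advance()
    g <- term_iri(advance())
    expect("lbrace")
    repeat {
      t <- peek()
      if (is.null(t)) np_error("unterminated graph block", "np_parse_error")
      if (t$type == "rbrace") { advance(); break }
      parse_triples(g)
      nx <- peek()
      if (!is.null(nx) && nx$type == "dot") advance()
    }
    nx <- peek()
    if (!is.null(nx) && nx$type == "dot") advance()
  }

  while (!is.null(peek())) {
    t <- peek()
    if (t$type == "at_prefix") {
      advance()
      pn <- expect("pname")
      if (!endsWith(pn$value, ":")) {
        np_error(sprintf("malformed prefix declaration at line %d", pn$line),
                 "np_parse_error")
      }
      ns <- expect("iriref")
      nx <- peek()
      if (!is.null(nx) && nx$type == "dot") advance()
      prefixes[[substr(pn$value, 1, nchar(pn$value) - 1L)]] <- ns$value
      next
    }
    if (dialect == "trig") {
      # lookahead: '<iri> {' or 'GRAPH <iri> {' opens a graph; else triples
      if (t$type == "kw_graph") { parse_graph_block(); next }
      if (t$type %in% c("iriref", "pname") &&
          pos + 1L <= length(tokens) && tokens[[pos + 1L]]$type == "lbrace") {
        parse_graph_block(); next
      }
    }
    parse_triples(default_graph)
    nx <- peek()
    if (!is.null(nx) && nx$type == "dot") advance() else if (!is.null(nx)) {
      np_error(sprintf("parse error at line %d: expected '.'", nx$line),
               "np_parse_error")
    }
  }
  list(quads = do.call(rbind_quads, quads), prefixes = prefixes)
}

#' Parse an RDF document into a graph bundle
#'
#' Accepts the package's own N-Quads and TriG output plus a Turtle subset
#' (prefix declarations, predicate/object lists, `a`, quoted literals with
#' language tags or datatypes) for fixture ontologies. Blank nodes are not
#' part of the grammar.
#'
#' @param text Document text (single string) or a character vector of lines.
#' @param dialect `"nquads"`, `"trig"`, or `"turtle"`.
#' @param default_graph Graph IRI assigned to Turtle triples (and TriG triples
#'   outside any graph block).
#' @return A [graph_bundle()].
#' @export
read_quads <- function(text, dialect = c("nquads", "trig", "turtle"),
                       default_graph = "urn:x-nanopubr:default-graph") {
  dialect <- match.arg(dialect)
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  if (dialect == "nquads") {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    keep <- which(!grepl("^\\s*(#|$)", lines))
    rows <- lapply(keep, function(i) parse_nq_line(lines[[i]], i))
    return(graph_bundle(do.call(rbind_quads, rows)))
  }
  parsed <- trig_parser(tokenize_trig(text),
                        dialect = if (dialect == "turtle") "turtle" else "trig",
                        default_graph = as.character(iri(default_graph)))
  graph_bundle(parsed$quads, parsed$prefixes)
}

#' Read an RDF file, guessing the dialect from the extension
#'
#' @param path File path; `.nq` is read as N-Quads, `.trig` as TriG, `.ttl`
#'   as Turtle.
#' @param ... Passed to [read_quads()].
#' @return A [graph_bundle()].
#' @export
read_rdf_file <- function(path, ...) {
  if (!file.exists(path)) {
    np_error(sprintf("no such file: %s", path), "np_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  dialect <- switch(ext, nq = "nquads", nquads = "nquads",
                    trig = "trig", ttl = "turtle", turtle = "turtle",
                    np_error(sprintf("cannot guess RDF dialect of '%s'", path),
                             "np_io_error"))
  read_quads(readLines(path, warn = FALSE), dialect = dialect, ...)
}

#' Write an RDF file, guessing the dialect from the extension
#'
#' @param bundle A [graph_bundle()].
#' @param path Output path (`.nq` or `.trig`; Turtle output is written as
#'   TriG-without-graphs via `.ttl`).
#' @return `path`, invisibly.
#' @export
write_rdf_file <- function(bundle, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nq", "nquads")) {
    txt <- write_quads(bundle, "nquads")
  } else if (ext == "trig") {
    txt <- write_quads(bundle, "trig")
  } else if (ext %in% c("ttl", "turtle")) {
    txt <- write_turtle(bundle)
  } else {
    np_error(sprintf("cannot guess RDF dialect of '%s'", path), "np_io_error")
  }
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Serialize a bundle as Turtle (graph membership dropped)
#'
#' Used for fixture ontologies, which are single-graph by construction.
#'
#' @param bundle A [graph_bundle()].
#' @return Turtle text.
#' @export
write_turtle <- function(bundle) {
  stopifnot(inherits(bundle, "graph_bundle"))
  quads <- bundle$quads
  prefixes <- bundle$prefixes
  out <- character(0)
  if (length(prefixes) > 0) {
    out <- c(out, paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> ."), "")
  }
  if (nrow(quads) > 0) {
    key <- paste(quads$s, quads$p)
    quads <- quads[order(key, method = "radix"), , drop = FALSE]
    for (i in seq_len(nrow(quads))) {
      out <- c(out, paste0(
        compact_term(quads$s[i], prefixes), " ",
        compact_term(quads$p[i], prefixes), " ",
        format_object_trig(quads[i, ], prefixes), " ."))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
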