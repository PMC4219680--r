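# Minimal MathML <-> R expression translation for SBML kinetic laws.
# Only the arithmetic subset that kinetic laws actually use is supported;
# anything else is a hard error naming the element, never a silent guess.

.mathml_ops <- c(plus = "+", minus = "-", times = "*", divide = "/",
                 power = "^")
.mathml_funs <- c(exp = "exp", ln = "log", abs = "abs",
                  floor = "floor", ceiling = "ceiling")

#' Parse a MathML node into an R expression
#'
#' Translates the arithmetic subset of MathML content markup used in SBML
#' kinetic laws (`apply` with plus/minus/times/divide/power, `ci`, `cn`,
#' `exp`, `ln`, `abs`, `floor`, `ceiling`, `pi`, `exponentiale`) into an R
#' call tree that can be evaluated against species amounts and parameters.
#'
#' @param node an `xml2` node: either the `<math>` element or its child.
#' @return an R language object (call, name, or numeric).
#' @keywords internal
#' @noRd
parse_mathml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L)
      stop("MathML <math> must contain exactly one expression", call. = FALSE)
    return(parse_mathml(kids[[1L]]))
  }
  if (nm == "ci") {
    sym <- trimws(xml2::xml_text(node))
    if (!nzchar(sym)) stop("empty <ci> in MathML", call. = FALSE)
    return(as.name(sym))
  }
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    txt <- trimws(xml2::xml_text(node))
    if (!is.na(type) && type == "e-notation") {
      # mantissa and exponent separated by <sep/>; xml_text concatenates
      parts <- strsplit(txt, "[[:space:]]+")[[1L]]
      parts <- parts[nzchar(parts)]
      if (length(parts) != 2L)
        stop("malformed e-notation <cn>: ", txt, call. = FALSE)
      return(as.numeric(parts[1L]) * 10^as.numeric(parts[2L]))
    }
    if (!is.na(type) && type == "rational") {
      parts <- strsplit(txt, "[[:space:]]+")[[1L]]
      parts <- parts[nzchar(parts)]
      if (length(parts) != 2L)
        stop("malformed rational <cn>: ", txt, call. = FALSE)
      return(as.numeric(parts[1L]) / as.numeric(parts[2L]))
    }
    val <- suppressWarnings(as.numeric(txt))
    if (is.na(val)) stop("non-numeric <cn>: ", txt, call. = FALSE)
    return(val)
  }
  if (nm == "pi") return(pi)
  if (nm == "exponentiale") return(exp(1))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    if (length(kids) < 2L)
      stop("MathML <apply> with no arguments", call. = FALSE)
    op <- xml2::xml_name(kids[[1L]])
    args <- lapply(kids[-1L], parse_mathml)
    if (op %in% names(.mathml_ops)) {
      rop <- .mathml_ops[[op]]
      if (op == "minus" && length(args) == 1L)
        return(call("-", args[[1L]]))
      if (length(args) == 1L) return(args[[1L]])
      return(Reduce(function(a, b) call(rop, a, b), args))
    }
    if (op %in% names(.mathml_funs)) {
      if (length(args) != 1L)
        stop("MathML <", op, "> expects one argument", call. = FALSE)
      return(call(.mathml_funs[[op]], args[[1L]]))
    }
    if (op == "root") {
      if (length(args) == 1L) return(call("sqrt", args[[1L]]))
      stop("MathML <root> with degree is not supported", call. = FALSE)
    }
    stop("unsupported MathML operator <", op, ">", call. = FALSE)
  }
  stop("unsupported MathML element <", nm, ">", call. = FALSE)
}

#' Serialize an R expression back to MathML content markup
#' @param e R language object produced by [parse_mathml()] or user code.
#' @return character scalar of MathML (without the `<math>` wrapper).
#' @keywords internal
#' @noRd
deparse_mathml <- function(e) {
  if (is.numeric(e)) {
    if (length(e) != 1L) stop("vector constants cannot be serialized")
    if (e == floor(e) && abs(e) < 1e15)
      return(sprintf("<cn type=\"integer\"> %d </cn>", as.integer(e)))
    return(sprintf("<cn> %s </cn>", format(e, digits = 17)))
  }
  if (is.name(e)) return(sprintf("<ci> %s </ci>", as.character(e)))
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    args <- as.list(e)[-1L]
    inner <- paste(vapply(args, deparse_mathml, character(1)), collapse = "")
    if (fn %in% .mathml_ops) {
      tag <- names(.mathml_ops)[match(fn, .mathml_ops)]
      return(sprintf("<apply><%s/>%s</apply>", tag, inner))
    }
    if (fn %in% .mathml_funs) {
      tag <- names(.mathml_funs)[match(fn, .mathml_funs)]
      return(sprintf("<apply><%s/>%s</apply>", tag, inner))
    }
    if (fn == "sqrt")
      return(sprintf("<apply><root/>%s</apply>", inner))
    if (fn == "(") return(deparse_mathml(args[[1L]]))
    stop("cannot serialize call to `", fn, "` as MathML", call. = FALSE)
  }
  stop("cannot serialize object of class ", class(e)[1L], " as MathML",
       call. = FALSE)
}

#' Evaluate a kinetic-law expression against a model state
#'
#' @param expr R language object (from [parse_mathml()]).
#' @param values named numeric vector/list: species amounts, parameters and
#'   compartment sizes, merged.
#' @return numeric scalar; negative evaluations are clamped to 0 with a
#'   warning (rate laws must not be negative for stochastic firing).
#' @keywords internal
#' @noRd
eval_kinetic_math <- function(expr, values) {
  vars <- all.vars(expr)
  missing <- setdiff(vars, names(values))
  if (length(missing))
    stop("kinetic law references unknown symbol(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  v <- eval(expr, envir = as.list(values), enclos = baseenv())
  if (!is.finite(v)) return(0)
  if (v < 0) {
    warning("kinetic law evaluated negative (", format(v),
            "); clamped to 0", call. = FALSE)
    return(0)
  }
  v
}
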