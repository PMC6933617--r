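## Standalone single-page HTML report. The full JSON report model is
## embedded verbatim in the page and a small inline JS/SVG layer renders
## the interactive figures from it, so every number shown is byte-identical
## to the JSON report and the file needs no network access to view.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write the standalone HTML report
#'
#' One self-contained HTML file with interactive figures (genome-scale
#' coverage per chromosome, BED-region coverage when a BED was given, the
#' duplication histogram, and pre/post mismatch-rate bars) plus the summary
#' table. The JSON report model is embedded in the page and all figures are
#' rendered from it client-side, so HTML and JSON agree on every number.
#'
#' @param model Report model from [finalize_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_html_report <- function(model, path) {
  json <- report_json_string(model)
  has_bed <- !is.null(model$bed_regions)
  page <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n",
    "<title>consensr report</title>\n<style>\n",
    "body{font-family:sans-serif;margin:2em;max-width:960px}\n",
    "h1{font-size:1.4em}h2{font-size:1.1em;margin-top:1.6em}\n",
    "table{border-collapse:collapse}td,th{border:1px solid #ccc;",
    "padding:4px 10px;text-align:right}th{background:#f0f0f0}\n",
    "svg{background:#fafafa;border:1px solid #ddd}\n",
    ".bar:hover{fill:#d62728}\n</style>\n</head>\n<body>\n",
    "<h1>Consensus read generation report</h1>\n",
    "<h2>Summary</h2>\n<div id=\"summary\"></div>\n",
    "<h2>Pre/post filtering</h2>\n<div id=\"phases\"></div>\n",
    "<h2>Duplication histogram</h2>\n<div id=\"dup\"></div>\n",
    "<h2>Mismatch rate</h2>\n<div id=\"mismatch\"></div>\n",
    "<h2>Genome-scale coverage</h2>\n",
    "<select id=\"chromsel\"></select>\n<div id=\"coverage\"></div>\n",
    if (has_bed) {
      "<h2>Capture-region coverage</h2>\n<div id=\"bed\"></div>\n"
    } else "",
    "<script type=\"application/json\" id=\"report-data\">\n",
    json,
    "\n</script>\n<script>\n", report_js(has_bed), "\n</script>\n",
    "</body>\n</html>\n")
  ok <- tryCatch({
    writeLines(page, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write HTML report to '%s'", path))
  invisible(path)
}

## inline charting layer: tables + SVG bar/line charts with hover titles
report_js <- function(has_bed) {
  paste0("
var R = JSON.parse(document.getElementById('report-data').textContent);
function el(tag, attrs, text) {
  var ns = 'http://www.w3.org/2000/svg';
  var e = ['svg','rect','line','polyline','text','title','g']
            .indexOf(tag) >= 0 ? document.createElementNS(ns, tag)
                               : document.createElement(tag);
  for (var k in (attrs || {})) e.setAttribute(k, attrs[k]);
  if (text !== undefined) e.textContent = text;
  return e;
}
function kvTable(obj) {
  var t = el('table');
  for (var k in obj) {
    var tr = el('tr');
    tr.appendChild(el('th', {}, k));
    tr.appendChild(el('td', {}, obj[k] === null ? 'null'
                                                : JSON.stringify(obj[k])));
    t.appendChild(tr);
  }
  return t;
}
function phaseTable(pre, post) {
  var t = el('table');
  var hr = el('tr');
  ['metric','pre','post'].forEach(function(h){hr.appendChild(el('th',{},h));});
  t.appendChild(hr);
  for (var k in pre) {
    var tr = el('tr');
    tr.appendChild(el('th', {}, k));
    [pre[k], post[k]].forEach(function(v){
      tr.appendChild(el('td', {}, v === null ? 'null' : JSON.stringify(v)));
    });
    t.appendChild(tr);
  }
  return t;
}
function barChart(labels, values, w, h, color) {
  var svg = el('svg', {width: w, height: h});
  var max = Math.max.apply(null, values.concat([1]));
  var bw = Math.max(2, Math.floor((w - 40) / Math.max(1, values.length)) - 2);
  values.forEach(function(v, i) {
    var bh = (h - 30) * v / max;
    var r = el('rect', {class:'bar', x: 30 + i * (bw + 2),
                        y: h - 20 - bh, width: bw, height: bh, fill: color});
    r.appendChild(el('title', {}, labels[i] + ': ' + v));
    svg.appendChild(r);
    if (values.length <= 30)
      svg.appendChild(el('text', {x: 30 + i * (bw + 2) + bw / 2, y: h - 6,
        'font-size': 10, 'text-anchor': 'middle'}, labels[i]));
  });
  svg.appendChild(el('text', {x: 2, y: 12, 'font-size': 10}, max));
  return svg;
}
document.getElementById('summary').appendChild(kvTable(R.summary));
document.getElementById('phases')
  .appendChild(phaseTable(R.pre_filtering, R.post_filtering));
var sizes = Object.keys(R.duplication_histogram);
document.getElementById('dup').appendChild(
  barChart(sizes, sizes.map(function(k){return R.duplication_histogram[k];}),
           640, 200, '#1f77b4'));
document.getElementById('mismatch').appendChild(
  barChart(['pre','post'],
           [R.pre_filtering.mismatch_rate || 0,
            R.post_filtering.mismatch_rate || 0], 200, 160, '#ff7f0e'));
var chroms = R.coverage.chromosomes;
var sel = document.getElementById('chromsel');
chroms.forEach(function(c, i) {
  sel.appendChild(el('option', {value: i}, c.name));
});
function drawCoverage(i) {
  var holder = document.getElementById('coverage');
  holder.innerHTML = '';
  var c = chroms[i];
  var labels = c.pre.map(function(_, j) {
    return c.name + ':' + (j * R.coverage.bin_width);
  });
  var g = el('div');
  g.appendChild(el('div', {}, 'pre (aligned bases per ' +
                              R.coverage.bin_width + ' bp bin)'));
  g.appendChild(barChart(labels, c.pre, 640, 150, '#1f77b4'));
  g.appendChild(el('div', {}, 'post'));
  g.appendChild(barChart(labels, c.post, 640, 150, '#2ca02c'));
  holder.appendChild(g);
}
sel.addEventListener('change', function() { drawCoverage(+sel.value); });
if (chroms.length) drawCoverage(0);
",
    if (has_bed) "
var bed = R.bed_regions;
var bl = bed.map(function(b){return b.chrom + ':' + b.start + '-' + b.end;});
var bdiv = document.getElementById('bed');
bdiv.appendChild(el('div', {}, 'mean depth pre'));
bdiv.appendChild(barChart(bl,
  bed.map(function(b){return b.mean_depth_pre;}), 640, 150, '#1f77b4'));
bdiv.appendChild(el('div', {}, 'mean depth post'));
bdiv.appendChild(barChart(bl,
  bed.map(function(b){return b.mean_depth_post;}), 640, 150, '#2ca02c'));
" else "")
}
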