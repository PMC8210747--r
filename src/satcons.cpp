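#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static inline char comp(char b) {
    switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
    }
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) c = comp(c);
    return r;
}

// ---------------------------------------------------------------------------
// monomer extraction: best 52-nt window vs any rotation of the consensus;
// if identity >= min_identity, lock phase and emit every complete in-phase
// window of the read. Both strands are scanned.
// ---------------------------------------------------------------------------

static void extract_one_strand(const std::string &read,
                               const std::vector<std::string> &rots,
                               double min_identity,
                               double min_window_identity,
                               std::vector<std::string> &out) {
    const int L = (int) rots[0].size();
    const int n = (int) read.size();
    if (n < L) return;
    const int maxmm_allowed = L - (int) std::ceil(min_identity * L);
    int best_mm = L + 1, best_w = -1, best_r = -1;
    for (int w = 0; w + L <= n; ++w) {
        for (size_t r = 0; r < rots.size(); ++r) {
            const char *a = read.data() + w;
            const char *b = rots[r].data();
            int mm = 0;
            // early exit once this rotation cannot beat the current best
            int lim = std::min(best_mm - 1, maxmm_allowed);
            for (int k = 0; k < L; ++k) {
                if (a[k] != b[k] && ++mm > lim) break;
            }
            if (mm < best_mm) { best_mm = mm; best_w = w; best_r = (int) r; }
        }
    }
    if (best_w < 0 || best_mm > maxmm_allowed) return;
    // the best window starts at consensus position best_r, so monomer
    // boundaries fall at read positions congruent to best_w - best_r:
    // in-phase windows are complete monomers in the consensus frame
    int phase = ((best_w - best_r) % L + L) % L;
    const std::string &frame = rots[0];
    for (int p = phase; p + L <= n; p += L) {
        if (min_window_identity > 0.0) {
            int mm = 0;
            for (int k = 0; k < L; ++k)
                if (read[p + k] != frame[k]) ++mm;
            if ((double) (L - mm) / L < min_window_identity) continue;
        }
        out.push_back(read.substr(p, L));
    }
}

// [[Rcpp::export(name = ".cppExtractMonomers")]]
CharacterVector cpp_extract_monomers(CharacterVector reads,
                                     std::string consensus,
                                     double min_identity,
                                     double min_window_identity) {
    const int L = (int) consensus.size();
    std::vector<std::string> rots(L);
    std::string dbl = consensus + consensus;
    for (int r = 0; r < L; ++r)
        rots[r] = dbl.substr(r, L);
    std::vector<std::string> out;
    for (int i = 0; i < reads.size(); ++i) {
        std::string rd = as<std::string>(reads[i]);
        extract_one_strand(rd, rots, min_identity, min_window_identity,
                           out);
        std::string rc = revcomp(rd);
        extract_one_strand(rc, rots, min_identity, min_window_identity,
                           out);
    }
    return wrap(out);
}

// [[Rcpp::export(name = ".cppCanonicalRotation")]]
CharacterVector cpp_canonical_rotation(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::string dbl = s + s;
        int n = (int) s.size();
        int best = 0;
        for (int r = 1; r < n; ++r) {
            if (dbl.compare(r, n, dbl, best, n) < 0) best = r;
        }
        out[i] = dbl.substr(best, n);
    }
    return out;
}

// ---------------------------------------------------------------------------
// read mapper: k-mer seeded, banded local (Smith-Waterman) alignment against
// a set of references; best-scoring candidate wins, ties resolved by
// reference order then leftmost position.  Depth counts base-aligned
// columns only (deletions in the read leave no depth).
// ---------------------------------------------------------------------------

struct Aln {
    int score = -1, ref = -1, strand = 0;
    int ref_start = -1, ref_end = -1;   // 0-based half-open
    int matches = 0, columns = 0;
    std::vector<std::pair<int, char>> bases;  // (ref pos 0-based, read base)
};

static const int MA = 2, MM = -3, GP = -4;

// banded SW of read vs ref around diagonal 'diag' (refpos - readpos)
static void banded_sw(const std::string &read, const std::string &ref,
                      int diag, int band, Aln &best, int ref_id,
                      int strand) {
    const int m = (int) read.size(), L = (int) ref.size();
    const int W = 2 * band + 1;
    // S[i][k] where k indexes j = diag + (i-1) ... offset within band:
    // j = i + diag + (k - band), valid when 0 <= j < L  (0-based j)
    std::vector<int> S((m + 1) * W, 0);
    std::vector<int8_t> D((m + 1) * W, 0);  // 0 stop, 1 diag, 2 up, 3 left
    int bs = 0, bi = -1, bk = -1;
    for (int i = 1; i <= m; ++i) {
        for (int k = 0; k < W; ++k) {
            int j = i - 1 + diag + (k - band);  // 0-based ref index
            if (j < 0 || j >= L) { S[i * W + k] = 0; D[i * W + k] = 0; continue; }
            int sc = 0; int8_t dd = 0;
            int sub = (read[i - 1] == ref[j]) ? MA : MM;
            int v = S[(i - 1) * W + k] + sub;  // same k: j shifts with i
            if (v > sc) { sc = v; dd = 1; }
            if (k + 1 < W) {  // gap in ref (read base unaligned): i-1, same j
                v = S[(i - 1) * W + (k + 1)] + GP;
                if (v > sc) { sc = v; dd = 2; }
            }
            if (k - 1 >= 0) {  // gap in read (ref base skipped): same i, j-1
                v = S[i * W + (k - 1)] + GP;
                if (v > sc) { sc = v; dd = 3; }
            }
            S[i * W + k] = sc; D[i * W + k] = dd;
            if (sc > bs) { bs = sc; bi = i; bk = k; }
        }
    }
    if (bs <= best.score) return;  // strict: first candidate wins ties
    // traceback
    Aln a; a.score = bs; a.ref = ref_id; a.strand = strand;
    int i = bi, k = bk;
    int matches = 0, columns = 0;
    int ref_end = bi - 1 + diag + (bk - band) + 1;  // half-open
    std::vector<std::pair<int, char>> bases;
    while (i > 0 && D[i * W + k] != 0) {
        int j = i - 1 + diag + (k - band);
        int8_t dd = D[i * W + k];
        if (dd == 1) {
            if (read[i - 1] == ref[j]) ++matches;
            bases.push_back(std::make_pair(j, read[i - 1]));
            ++columns; --i;
        } else if (dd == 2) { ++columns; --i; k = k + 1; }
        else { ++columns; k = k - 1; }
    }
    int ref_start = i + diag + (k - band);
    a.ref_start = ref_start; a.ref_end = ref_end;
    a.matches = matches; a.columns = columns; a.bases = bases;
    best = a;
}

static inline int base_row(char b) {
    switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
}

// [[Rcpp::export(name = ".cppMapReads")]]
List cpp_map_reads(CharacterVector reads, CharacterVector ref_seqs,
                   double min_identity, int min_overlap, int seed_len,
                   int band) {
    const int nref = ref_seqs.size();
    std::vector<std::string> refs(nref);
    for (int r = 0; r < nref; ++r) refs[r] = as<std::string>(ref_seqs[r]);
    // seed index over all references
    std::unordered_multimap<uint64_t, std::pair<int, int>> index;
    const uint64_t mask = (seed_len >= 32) ? ~0ULL
        : ((1ULL << (2 * seed_len)) - 1ULL);
    for (int r = 0; r < nref; ++r) {
        const std::string &s = refs[r];
        uint64_t h = 0; int run = 0;
        for (size_t p = 0; p < s.size(); ++p) {
            int c = base_row(s[p]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t) c) & mask;
            if (++run >= seed_len)
                index.insert(std::make_pair(
                    h, std::make_pair(r, (int) p - seed_len + 1)));
        }
    }
    const int n = reads.size();
    IntegerVector o_ref(n, NA_INTEGER), o_start(n, NA_INTEGER),
        o_end(n, NA_INTEGER), o_matches(n, NA_INTEGER),
        o_columns(n, NA_INTEGER);
    CharacterVector o_strand(n, NA_STRING);
    NumericVector o_ident(n, NA_REAL);
    // depth + base counts per reference
    List depthL(nref), baseL(nref);
    std::vector<std::vector<double>> depth(nref);
    std::vector<std::vector<double>> bc(nref);
    for (int r = 0; r < nref; ++r) {
        depth[r].assign(refs[r].size(), 0.0);
        bc[r].assign(4 * refs[r].size(), 0.0);
    }
    std::vector<std::pair<int, int>> cands;  // (ref, diag)
    for (int q = 0; q < n; ++q) {
        std::string fwd = as<std::string>(reads[q]);
        std::string rev = revcomp(fwd);
        Aln best;
        for (int strand = 0; strand < 2; ++strand) {
            const std::string &rd = (strand == 0) ? fwd : rev;
            const int m = (int) rd.size();
            if (m < seed_len) continue;
            cands.clear();
            uint64_t h = 0; int run = 0;
            for (int p = 0; p < m; ++p) {
                int c = base_row(rd[p]);
                if (c < 0) { run = 0; h = 0; continue; }
                h = ((h << 2) | (uint64_t) c) & mask;
                if (++run >= seed_len) {
                    auto rng = index.equal_range(h);
                    for (auto it = rng.first; it != rng.second; ++it) {
                        int rp = it->second.second;
                        int rdp = p - seed_len + 1;
                        cands.push_back(std::make_pair(
                            it->second.first, rp - rdp));
                    }
                }
            }
            std::sort(cands.begin(), cands.end());
            cands.erase(std::unique(cands.begin(), cands.end()),
                        cands.end());
            // merge diagonals closer than the band (same alignment)
            int last_ref = -1, last_diag = INT32_MIN;
            for (auto &cd : cands) {
                if (cd.first == last_ref && cd.second - last_diag <= band)
                    continue;
                last_ref = cd.first; last_diag = cd.second;
                banded_sw(rd, refs[cd.first], cd.second, band, best,
                          cd.first, strand);
            }
        }
        if (best.score < 0) continue;
        double ident = best.columns > 0 ?
            (double) best.matches / best.columns : 0.0;
        if (best.columns < min_overlap || ident < min_identity) continue;
        o_ref[q] = best.ref + 1;
        o_start[q] = best.ref_start + 1;
        o_end[q] = best.ref_end;
        o_strand[q] = (best.strand == 0) ? "+" : "-";
        o_matches[q] = best.matches;
        o_columns[q] = best.columns;
        o_ident[q] = ident;
        int r = best.ref;
        size_t L = refs[r].size();
        for (auto &pb : best.bases) {
            int j = pb.first;
            if (j < 0 || (size_t) j >= L) continue;
            depth[r][j] += 1.0;
            int row = base_row(pb.second);
            if (row >= 0) bc[r][4 * j + row] += 1.0;
        }
    }
    for (int r = 0; r < nref; ++r) {
        depthL[r] = wrap(depth[r]);
        NumericMatrix m(4, (int) refs[r].size());
        for (size_t j = 0; j < refs[r].size(); ++j)
            for (int b = 0; b < 4; ++b) m(b, (int) j) = bc[r][4 * j + b];
        baseL[r] = m;
    }
    return List::create(
        _["ref"] = o_ref, _["refStart"] = o_start, _["refEnd"] = o_end,
        _["strand"] = o_strand, _["matches"] = o_matches,
        _["columns"] = o_columns, _["identity"] = o_ident,
        _["depth"] = depthL, _["baseCounts"] = baseL);
}

// ---------------------------------------------------------------------------
// wraparound tandem-array detection: local alignment of a read against the
// infinite cyclic concatenation of the monomer, unit costs (match +1,
// mismatch/indel -1).  Maximal-scoring segments are peeled off greedily,
// recursing on the flanking read segments.
// ---------------------------------------------------------------------------

struct ArrayHit {
    int start, end;       // 0-based half-open read coords
    int edits, columns, score, strand;
};

struct PathCol {
    int read_pos;         // read base consumed (-1 for monomer-gap column)
    bool edit;
    int delta;            // score contribution of this column
};

// DP on read[lo, hi); returns true when a candidate scoring >= min_score
// exists, filling hit and its alignment path (noise not yet filtered)
static bool wraparound_best(const std::string &read, int lo, int hi,
                            const std::string &mono, int min_score,
                            int mm_pen, int gap_pen, ArrayHit &hit,
                            std::vector<PathCol> &path) {
    const int L = (int) mono.size();
    const int n = hi - lo;
    if (n <= 0) return false;
    std::vector<int32_t> S((size_t)(n + 1) * L, 0);
    std::vector<int8_t> D((size_t)(n + 1) * L, 0);  // 0 stop,1 diag,2 up,3 left
    int bs = 0, bi = -1, bj = -1;
    for (int i = 1; i <= n; ++i) {
        char xb = read[lo + i - 1];
        int32_t *Sc = &S[(size_t) i * L];
        int32_t *Sp = &S[(size_t)(i - 1) * L];
        int8_t *Dc = &D[(size_t) i * L];
        // two passes handle the cyclic within-column dependency
        for (int pass = 0; pass < 2; ++pass) {
            for (int j = 0; j < L; ++j) {
                int jm1 = (j == 0) ? L - 1 : j - 1;
                int sc = 0; int8_t dd = 0;
                int v = Sp[jm1] + ((xb == mono[j]) ? 1 : -mm_pen);
                if (v > sc) { sc = v; dd = 1; }
                v = Sp[j] - gap_pen;      // read base vs gap
                if (v > sc) { sc = v; dd = 2; }
                v = Sc[jm1] - gap_pen;    // monomer base vs gap
                if (v > sc) { sc = v; dd = 3; }
                if (pass == 0 || sc > Sc[j]) { Sc[j] = sc; Dc[j] = dd; }
            }
        }
        for (int j = 0; j < L; ++j)
            if (Sc[j] > bs) { bs = Sc[j]; bi = i; bj = j; }
    }
    if (bs < min_score) return false;
    // traceback, recording the path
    path.clear();
    int i = bi, j = bj, edits = 0, columns = 0;
    while (i > 0 && D[(size_t) i * L + j] != 0) {
        int8_t dd = D[(size_t) i * L + j];
        int jm1 = (j == 0) ? (int) mono.size() - 1 : j - 1;
        PathCol pc;
        if (dd == 1) {
            pc.edit = (read[lo + i - 1] != mono[j]);
            pc.read_pos = lo + i - 1;
            pc.delta = pc.edit ? -mm_pen : 1;
            if (pc.edit) ++edits;
            ++columns; --i; j = jm1;
        } else if (dd == 2) {
            pc.edit = true; pc.read_pos = lo + i - 1; pc.delta = -gap_pen;
            ++edits; ++columns; --i;
        } else {
            pc.edit = true; pc.read_pos = -1; pc.delta = -gap_pen;
            ++edits; ++columns; j = jm1;
        }
        path.push_back(pc);
    }
    std::reverse(path.begin(), path.end());
    hit.start = lo + i; hit.end = lo + bi;
    hit.edits = edits; hit.columns = columns; hit.score = bs;
    return true;
}

// X-drop segmentation of an alignment path: split wherever the running
// score falls more than xdrop below its peak (a long low-identity bridge
// between two arrays), returning per-segment hits
static std::vector<ArrayHit> xdrop_segments(const std::vector<PathCol> &path,
                                            int xdrop) {
    std::vector<ArrayHit> segs;
    size_t n = path.size(), segStart = 0;
    auto emit = [&](size_t from, size_t to) {
        int rstart = -1, rend = -1, edits = 0, columns = 0, score = 0;
        for (size_t k = from; k <= to; ++k) {
            if (path[k].read_pos >= 0) {
                if (rstart < 0) rstart = path[k].read_pos;
                rend = path[k].read_pos;
            }
            if (path[k].edit) ++edits;
            ++columns; score += path[k].delta;
        }
        if (rstart >= 0) {
            ArrayHit h;
            h.start = rstart; h.end = rend + 1;
            h.edits = edits; h.columns = columns; h.score = score;
            segs.push_back(h);
        }
    };
    while (segStart < n) {
        while (segStart < n && path[segStart].delta < 0) ++segStart;
        if (segStart >= n) break;
        int run = 0, peak = 0;
        size_t peakIdx = segStart;
        bool cut = false;
        for (size_t c = segStart; c < n; ++c) {
            run += path[c].delta;
            if (run > peak) { peak = run; peakIdx = c; }
            if (run < 0) {
                // net-negative prefix: this excursion is over
                if (peak > 0) emit(segStart, peakIdx);
                segStart = c + 1;
                cut = true;
                break;
            }
            if (peak - run > xdrop) {
                // score collapse: a low-identity bridge follows the peak
                emit(segStart, peakIdx);
                segStart = peakIdx + 1;
                cut = true;
                break;
            }
        }
        if (!cut) {
            if (peak > 0) emit(segStart, peakIdx);
            break;
        }
    }
    return segs;
}

// [[Rcpp::export(name = ".cppDetectArrays")]]
DataFrame cpp_detect_arrays(std::string read, std::string monomer,
                            double max_noise, int min_span,
                            int mm_pen, int gap_pen, int xdrop) {
    // an acceptable segment (noise <= max_noise over >= min_span columns)
    // scores at least span * (1 - (1 + maxpen) * max_noise)
    int maxpen = std::max(mm_pen, gap_pen);
    int min_score = std::max(
        1, (int) std::floor(min_span * (1.0 - (1.0 + maxpen) * max_noise)));
    std::vector<ArrayHit> hits;
    std::vector<PathCol> path;
    for (int strand = 0; strand < 2; ++strand) {
        std::string mono = (strand == 0) ? monomer : revcomp(monomer);
        std::vector<std::pair<int, int>> stack;
        stack.push_back(std::make_pair(0, (int) read.size()));
        while (!stack.empty()) {
            std::pair<int, int> seg = stack.back(); stack.pop_back();
            if (seg.second - seg.first < min_span) continue;
            ArrayHit h;
            if (!wraparound_best(read, seg.first, seg.second, mono,
                                 min_score, mm_pen, gap_pen, h, path))
                continue;
            if (h.end <= h.start) continue;
            // split the best alignment at internal score collapses
            // (low-identity bridges between arrays)
            std::vector<ArrayHit> parts = xdrop_segments(path, xdrop);
            for (size_t p = 0; p < parts.size(); ++p) {
                ArrayHit &ph = parts[p];
                if (ph.end <= ph.start) continue;
                double noise = ph.columns > 0 ?
                    (double) ph.edits / ph.columns : 1.0;
                if (ph.end - ph.start >= min_span && noise <= max_noise) {
                    ph.strand = strand;
                    hits.push_back(ph);
                } else if (ph.end - ph.start > 2 * min_span) {
                    // too noisy as a whole: split so cleaner
                    // sub-segments can still surface
                    int mid = (ph.start + ph.end) / 2;
                    stack.push_back(std::make_pair(ph.start, mid));
                    stack.push_back(std::make_pair(mid, ph.end));
                }
            }
            stack.push_back(std::make_pair(seg.first, h.start));
            stack.push_back(std::make_pair(h.end, seg.second));
        }
    }
    // greedy cross-strand overlap resolution: score desc, length desc,
    // leftmost
    std::sort(hits.begin(), hits.end(),
              [](const ArrayHit &a, const ArrayHit &b) {
                  if (a.score != b.score) return a.score > b.score;
                  int la = a.end - a.start, lb = b.end - b.start;
                  if (la != lb) return la > lb;
                  return a.start < b.start;
              });
    std::vector<ArrayHit> kept;
    for (auto &h : hits) {
        bool clash = false;
        for (auto &k : kept)
            if (h.start < k.end && k.start < h.end) { clash = true; break; }
        if (!clash) kept.push_back(h);
    }
    std::sort(kept.begin(), kept.end(),
              [](const ArrayHit &a, const ArrayHit &b) {
                  return a.start < b.start;
              });
    int m = (int) kept.size();
    IntegerVector st(m), en(m), ed(m), co(m), sc(m);
    CharacterVector sd(m);
    for (int i = 0; i < m; ++i) {
        st[i] = kept[i].start; en[i] = kept[i].end;
        ed[i] = kept[i].edits; co[i] = kept[i].columns;
        sc[i] = kept[i].score;
        sd[i] = kept[i].strand == 0 ? "+" : "-";
    }
    return DataFrame::create(
        _["start"] = st, _["end"] = en, _["edits"] = ed,
        _["columns"] = co, _["score"] = sc, _["strand"] = sd,
        _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// exhaustive minimum spanning weight (brute-force verifier, n <= 10)
// ---------------------------------------------------------------------------

static int dsu_find(std::vector<int> &p, int x) {
    while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
    return x;
}

static void enum_rec(int n, const std::vector<int> &u,
                     const std::vector<int> &v,
                     const std::vector<double> &w,
                     size_t next, int chosen, double weight,
                     std::vector<int> &picks, double &best) {
    if (chosen == n - 1) {
        std::vector<int> p(n);
        for (int i = 0; i < n; ++i) p[i] = i;
        int comp = n;
        for (int e : picks) {
            int a = dsu_find(p, u[e]), b = dsu_find(p, v[e]);
            if (a != b) { p[a] = b; --comp; }
        }
        if (comp == 1 && weight < best) best = weight;
        return;
    }
    if (next >= u.size()) return;
    if ((int) (u.size() - next) < n - 1 - chosen) return;
    if (weight >= best) return;  // weights are non-negative
    picks.push_back((int) next);
    enum_rec(n, u, v, w, next + 1, chosen + 1, weight + w[next], picks,
             best);
    picks.pop_back();
    enum_rec(n, u, v, w, next + 1, chosen, weight, picks, best);
}

// [[Rcpp::export(name = ".cppEnumMinSpanningWeight")]]
double cpp_enum_min_spanning_weight(int n, IntegerVector u0,
                                    IntegerVector v0, NumericVector w0) {
    if (n > 10) stop("exhaustive enumeration is limited to n <= 10");
    std::vector<int> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
    std::vector<double> w(w0.begin(), w0.end());
    double best = R_PosInf;
    std::vector<int> picks;
    enum_rec(n, u, v, w, 0, 0, 0.0, picks, best);
    return best;
}
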