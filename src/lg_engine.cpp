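// Multipoint inheritance-vector HMM for pedigree likelihoods (Lander-Green).
//
// State space: one bit per non-founder meiosis, reduced by founder phase
// symmetry (swapping a founder's two alleles leaves the likelihood invariant,
// so one meiosis per founder is pinned to 0).  Effective bit count is
// b = 2*nonfounders - founders-with-children.  Transitions between adjacent
// map positions are independent per-bit flips with probability theta; on the
// reduced space the kernel stays diagonal in the Walsh-Hadamard basis, with
// an extra (1-2*theta) factor for odd parity within each founder's meiosis
// group.  Marker emissions sum founder-allele assignments under HWE via the
// founder-allele graph (value forcing for homozygotes, two-colouring of the
// components linked by heterozygotes).  Trait emissions are tabulated once
// per affection vector as sparse counts over "keys" (disease-allele total
// among founder slots plus per-class affected/unaffected counts), so that a
// LOD for any trait model is a dot product.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

namespace {

struct LGFamily {
    int n = 0;                  // persons, topologically sorted
    int f = 0;                  // founders
    int nGroups = 0;            // founders with >= 1 child
    int beff = 0;               // reduced bit count
    int nV = 0;                 // 1 << beff
    std::vector<int> father, mother;    // -1 for founders
    std::vector<int> founderNo;         // 0..f-1 for founders, -1 otherwise
    std::vector<int> patBit, matBit;    // reduced bit index or -1 (fixed/founder)
    // per-v descent tables: founder slot of each person's two alleles
    std::vector<uint8_t> pslot, mslot;  // nV * n
    std::vector<uint8_t> pc;            // popcount per v
    std::vector<uint16_t> gpar;         // founder-group parity pattern per v
    // trait tables for the current affection vector
    std::vector<int> aff;               // 0/1/2
    int K = 0;
    std::vector<int64_t> keyPacked;     // K packed keys
    std::vector<int> crowPtr;           // CSR row pointers, length nV+1
    std::vector<int> ckey;
    std::vector<double> ccount;
    std::vector<double> W0;             // key weights under uniform inheritance
    // model tables (optional, for fixed-grid scans)
    int nmod = 0;
    std::vector<double> Tmat;           // nV * nmod, contiguous per state v
    std::vector<double> L0;             // per model
};

inline double slotProb(int allele, double p1) {
    return allele == 1 ? p1 : 1.0 - p1;
}

// P(observed genotypes at one marker | inheritance vector v), founder alleles
// summed out under HWE.  geno: per person -1/0/1/2 (count of allele 2).
double markerEmission(const LGFamily& fam, int v, const int* geno, double p1) {
    const int nslot = 2 * fam.f;
    int val[64];                      // 0 unset, 1, 2
    for (int s = 0; s < nslot; ++s) val[s] = 0;
    int ea[64], eb[64], ne = 0;       // "differ" edges from heterozygotes
    const uint8_t* ps = &fam.pslot[(size_t)v * fam.n];
    const uint8_t* ms = &fam.mslot[(size_t)v * fam.n];
    for (int i = 0; i < fam.n; ++i) {
        int g = geno[i];
        if (g < 0) continue;
        int a = ps[i], b = ms[i];
        if (g == 1) {
            if (a == b) return 0.0;
            ea[ne] = a; eb[ne] = b; ++ne;
        } else {
            int allele = (g == 0) ? 1 : 2;
            if (val[a] && val[a] != allele) return 0.0;
            if (val[b] && val[b] != allele) return 0.0;
            val[a] = val[b] = allele;
        }
    }
    // propagate forced values through differ-edges
    bool changed = true;
    while (changed) {
        changed = false;
        for (int e = 0; e < ne; ++e) {
            int a = ea[e], b = eb[e];
            if (val[a] && val[b]) {
                if (val[a] == val[b]) return 0.0;
            } else if (val[a]) {
                val[b] = 3 - val[a]; changed = true;
            } else if (val[b]) {
                val[a] = 3 - val[b]; changed = true;
            }
        }
    }
    double prob = 1.0;
    // forced slots
    for (int s = 0; s < nslot; ++s)
        if (val[s]) prob *= slotProb(val[s], p1);
    // remaining components of unset slots connected by differ-edges:
    // two admissible colourings, sum their probabilities
    int colour[64];
    for (int s = 0; s < nslot; ++s) colour[s] = -1;
    for (int e0 = 0; e0 < ne; ++e0) {
        int seed = ea[e0];
        if (val[seed] || colour[seed] >= 0) continue;
        // BFS over this component
        int stack[64], top = 0;
        colour[seed] = 0; stack[top++] = seed;
        double pr0 = 1.0, pr1 = 1.0;   // colour0 = allele1 vs colour0 = allele2
        int comp[64], nc = 0;
        while (top) {
            int s = stack[--top];
            comp[nc++] = s;
            for (int e = 0; e < ne; ++e) {
                int o = -1;
                if (ea[e] == s) o = eb[e];
                else if (eb[e] == s) o = ea[e];
                if (o < 0 || val[o]) continue;
                if (colour[o] < 0) { colour[o] = 1 - colour[s]; stack[top++] = o; }
                else if (colour[o] == colour[s]) return 0.0;  // odd cycle
            }
        }
        for (int c = 0; c < nc; ++c) {
            int s = comp[c];
            pr0 *= slotProb(colour[s] == 0 ? 1 : 2, p1);
            pr1 *= slotProb(colour[s] == 0 ? 2 : 1, p1);
        }
        prob *= (pr0 + pr1);
    }
    // untouched slots integrate to 1
    return prob;
}

void fwht(double* x, int bits) {
    const int nV = 1 << bits;
    for (int len = 1; len < nV; len <<= 1)
        for (int i = 0; i < nV; i += (len << 1))
            for (int j = i; j < i + len; ++j) {
                double u = x[j], w = x[j + len];
                x[j] = u + w;
                x[j + len] = u - w;
            }
}

// In-place application of the reduced-space transition kernel for one theta.
void applyTransition(const LGFamily& fam, double* x, double theta) {
    if (theta <= 0.0) return;
    const int nV = fam.nV;
    if (nV == 1) return;
    double pow1[32];
    pow1[0] = 1.0;
    double r = 1.0 - 2.0 * theta;
    for (int k = 1; k <= fam.beff; ++k) pow1[k] = pow1[k - 1] * r;
    // founder-group parity factor: (1-2theta) per odd-parity group
    const int nPat = 1 << fam.nGroups;
    std::vector<double> gprod(nPat, 1.0);
    for (int p = 1; p < nPat; ++p) {
        int bitsSet = __builtin_popcount((unsigned)p);
        gprod[p] = 1.0;
        for (int k = 0; k < bitsSet; ++k) gprod[p] *= r;
    }
    fwht(x, fam.beff);
    const double inv = 1.0 / nV;
    for (int v = 0; v < nV; ++v)
        x[v] *= pow1[fam.pc[v]] * gprod[fam.gpar[v]] * inv;
    fwht(x, fam.beff);
    // clip tiny negative round-off
    for (int v = 0; v < nV; ++v) if (x[v] < 0 && x[v] > -1e-12) x[v] = 0.0;
}

struct HMMState {
    std::vector<double> alpha;   // M * nV, normalized per marker
    std::vector<double> beta;    // M * nV, includes own emission, normalized
    std::vector<double> logs;    // log10 scale per marker (forward)
    double loglik10 = 0.0;
    int M = 0;
};

void runHMM(const LGFamily& fam, const IntegerMatrix& geno,
            const NumericVector& freq, const NumericVector& theta,
            HMMState& st) {
    const int M = geno.ncol(), nV = fam.nV;
    st.M = M;
    st.alpha.assign((size_t)M * nV, 0.0);
    st.beta.assign((size_t)M * nV, 0.0);
    st.logs.assign(M, 0.0);
    std::vector<double> E((size_t)M * nV);
    std::vector<int> g(fam.n);
    for (int m = 0; m < M; ++m) {
        for (int i = 0; i < fam.n; ++i) {
            int gi = geno(i, m);
            g[i] = (gi == NA_INTEGER) ? -1 : gi;
        }
        double p1 = freq[m];
        double tot = 0.0;
        double* e = &E[(size_t)m * nV];
        for (int v = 0; v < nV; ++v) {
            e[v] = markerEmission(fam, v, g.data(), p1);
            tot += e[v];
        }
        if (tot <= 0.0)
            stop("zero-probability genotype data at marker index %d "
                 "(Mendelian inconsistency not removed upstream)", m + 1);
    }
    std::vector<double> buf(nV);
    // forward
    double ll = 0.0;
    for (int m = 0; m < M; ++m) {
        double* a = &st.alpha[(size_t)m * nV];
        if (m == 0) {
            std::copy(E.data(), E.data() + nV, a);
        } else {
            std::copy(&st.alpha[(size_t)(m - 1) * nV],
                      &st.alpha[(size_t)(m - 1) * nV] + nV, buf.data());
            applyTransition(fam, buf.data(), theta[m - 1]);
            const double* e = &E[(size_t)m * nV];
            for (int v = 0; v < nV; ++v) a[v] = buf[v] * e[v];
        }
        double s = 0.0;
        for (int v = 0; v < nV; ++v) s += a[v];
        if (s <= 0.0) stop("forward pass vanished at marker index %d", m + 1);
        for (int v = 0; v < nV; ++v) a[v] /= s;
        st.logs[m] = std::log10(s);
        ll += st.logs[m];
    }
    st.loglik10 = ll - fam.beff * std::log10(2.0);
    // backward (beta includes own emission)
    for (int m = M - 1; m >= 0; --m) {
        double* b = &st.beta[(size_t)m * nV];
        const double* e = &E[(size_t)m * nV];
        if (m == M - 1) {
            std::copy(e, e + nV, b);
        } else {
            std::copy(&st.beta[(size_t)(m + 1) * nV],
                      &st.beta[(size_t)(m + 1) * nV] + nV, buf.data());
            applyTransition(fam, buf.data(), theta[m]);
            for (int v = 0; v < nV; ++v) b[v] = buf[v] * e[v];
        }
        double s = 0.0;
        for (int v = 0; v < nV; ++v) s += b[v];
        for (int v = 0; v < nV; ++v) b[v] /= s;
    }
}

// posterior inheritance distribution at one scan position.
// idx: marker interval (-1 before first, M-1 after last, else between idx and
// idx+1); thetaL/thetaR: recombination fractions to flanking markers.
void posteriorAt(const LGFamily& fam, const HMMState& st, int idx,
                 double thetaL, double thetaR, double* out) {
    const int nV = fam.nV, M = st.M;
    std::vector<double> left(nV), right(nV);
    if (idx < 0) {
        std::copy(&st.beta[0], &st.beta[0] + nV, right.data());
        applyTransition(fam, right.data(), thetaR);
        std::copy(right.begin(), right.end(), out);
    } else if (idx >= M - 1) {
        std::copy(&st.alpha[(size_t)(M - 1) * nV],
                  &st.alpha[(size_t)(M - 1) * nV] + nV, left.data());
        applyTransition(fam, left.data(), thetaL);
        std::copy(left.begin(), left.end(), out);
    } else {
        std::copy(&st.alpha[(size_t)idx * nV],
                  &st.alpha[(size_t)idx * nV] + nV, left.data());
        applyTransition(fam, left.data(), thetaL);
        std::copy(&st.beta[(size_t)(idx + 1) * nV],
                  &st.beta[(size_t)(idx + 1) * nV] + nV, right.data());
        applyTransition(fam, right.data(), thetaR);
        for (int v = 0; v < nV; ++v) out[v] = left[v] * right[v];
    }
    double s = 0.0;
    for (int v = 0; v < nV; ++v) s += out[v];
    if (s <= 0.0) stop("degenerate inheritance posterior at scan position");
    for (int v = 0; v < nV; ++v) out[v] /= s;
}

LGFamily* getFam(SEXP xp) {
    Rcpp::XPtr<LGFamily> ptr(xp);
    return ptr.get();
}

}  // namespace

// [[Rcpp::export(name = ".lgBuild")]]
SEXP lgBuild(IntegerVector father, IntegerVector mother, int bitLimit) {
    // father/mother: 1-based indices into the (topologically sorted) person
    // list, 0 for founders
    LGFamily* fam = new LGFamily();
    const int n = father.size();
    fam->n = n;
    fam->father.resize(n); fam->mother.resize(n);
    fam->founderNo.assign(n, -1);
    fam->patBit.assign(n, -1); fam->matBit.assign(n, -1);
    int f = 0;
    for (int i = 0; i < n; ++i) {
        fam->father[i] = father[i] - 1;
        fam->mother[i] = mother[i] - 1;
        if (fam->father[i] >= i || fam->mother[i] >= i)
            stop("persons must be sorted with parents before children");
        if ((fam->father[i] < 0) != (fam->mother[i] < 0))
            stop("person %d has exactly one parent in the family", i + 1);
        if (fam->father[i] < 0) fam->founderNo[i] = f++;
    }
    fam->f = f;
    if (f > 16) { delete fam; stop("more than 16 founders unsupported"); }
    // assign reduced bits: the first meiosis from each founder is fixed to 0
    std::vector<bool> founderSeen(n, false);
    std::vector<int> groupOf;     // per reduced bit: founder group or -1
    int bit = 0;
    std::vector<int> founderGroup(n, -1);
    int ng = 0;
    for (int i = 0; i < n; ++i) {
        if (fam->father[i] < 0) continue;
        for (int side = 0; side < 2; ++side) {
            int par = side == 0 ? fam->father[i] : fam->mother[i];
            int* slot = side == 0 ? &fam->patBit[i] : &fam->matBit[i];
            if (fam->founderNo[par] >= 0) {
                if (!founderSeen[par]) {
                    founderSeen[par] = true;
                    founderGroup[par] = ng++;
                    *slot = -1;              // fixed meiosis
                } else {
                    *slot = bit++;
                    groupOf.push_back(founderGroup[par]);
                }
            } else {
                *slot = bit++;
                groupOf.push_back(-1);
            }
        }
    }
    fam->nGroups = ng;
    if (ng > 16) { delete fam; stop("too many founder groups"); }
    fam->beff = bit;
    int braw = 0;
    for (int i = 0; i < n; ++i) if (fam->father[i] >= 0) braw += 2;
    braw -= ng;   // founder-symmetry-reduced bit size, 2n - f
    if (braw != bit) stop("internal bit accounting error");
    if (bit > bitLimit)
        stop("family bit-size %d exceeds limit %d", bit, bitLimit);
    if (bit > 24) { delete fam; stop("family too large for the engine"); }
    fam->nV = 1 << bit;
    const int nV = fam->nV;
    // descent tables
    fam->pslot.resize((size_t)nV * n);
    fam->mslot.resize((size_t)nV * n);
    fam->pc.resize(nV);
    fam->gpar.resize(nV);
    std::vector<uint16_t> bitGroupMask(bit, 0);
    for (int k = 0; k < bit; ++k)
        if (groupOf[k] >= 0) bitGroupMask[k] = (uint16_t)(1 << groupOf[k]);
    for (int v = 0; v < nV; ++v) {
        uint8_t* ps = &fam->pslot[(size_t)v * n];
        uint8_t* ms = &fam->mslot[(size_t)v * n];
        for (int i = 0; i < n; ++i) {
            if (fam->founderNo[i] >= 0) {
                ps[i] = (uint8_t)(2 * fam->founderNo[i]);
                ms[i] = (uint8_t)(2 * fam->founderNo[i] + 1);
            } else {
                for (int side = 0; side < 2; ++side) {
                    int par = side == 0 ? fam->father[i] : fam->mother[i];
                    int bidx = side == 0 ? fam->patBit[i] : fam->matBit[i];
                    int bv = bidx < 0 ? 0 : ((v >> bidx) & 1);
                    uint8_t s;
                    if (fam->founderNo[par] >= 0)
                        s = (uint8_t)(2 * fam->founderNo[par] + bv);
                    else
                        s = bv == 0 ? ps[par] : ms[par];
                    if (side == 0) ps[i] = s; else ms[i] = s;
                }
            }
        }
        fam->pc[v] = (uint8_t)__builtin_popcount((unsigned)v);
        uint16_t gp = 0;
        for (int k = 0; k < bit; ++k)
            if ((v >> k) & 1) gp ^= bitGroupMask[k];
        fam->gpar[v] = gp;
    }
    Rcpp::XPtr<LGFamily> ptr(fam, true);
    return ptr;
}

// [[Rcpp::export(name = ".lgInfo")]]
List lgInfo(SEXP xp) {
    LGFamily* fam = getFam(xp);
    return List::create(_["n"] = fam->n, _["founders"] = fam->f,
                        _["bits"] = fam->beff, _["states"] = fam->nV,
                        _["K"] = fam->K);
}

// Build the sparse trait-count table for an affection vector (0/1/2).
// Keys pack: disease-allele total d among the 2f founder slots, and counts of
// persons per (affection, trait-genotype class) with classes
// 0 copies / 1 paternal / 1 maternal / 2 copies / founder-heterozygote.
// A founder's own heterozygote class is kept separate because the parental
// origin of a founder allele is unknowable: under the founder-symmetry
// reduction the exact marginalization gives such a person the mean of the
// two origin-specific penetrances.
// [[Rcpp::export(name = ".lgSetAffection")]]
int lgSetAffection(SEXP xp, IntegerVector affection) {
    LGFamily* fam = getFam(xp);
    const int n = fam->n, nV = fam->nV, nslot = 2 * fam->f;
    if (affection.size() != n) stop("affection length mismatch");
    if (nslot > 24) stop("too many founder slots for trait table");
    fam->aff.assign(affection.begin(), affection.end());
    const int nS = 1 << nslot;
    std::unordered_map<int64_t, int> reg;
    fam->crowPtr.assign(nV + 1, 0);
    fam->ckey.clear(); fam->ccount.clear(); fam->keyPacked.clear();
    std::vector<int64_t> tmp(nS);
    // relevant persons: affection known
    std::vector<int> who;
    for (int i = 0; i < n; ++i) if (fam->aff[i]) who.push_back(i);
    for (int v = 0; v < nV; ++v) {
        const uint8_t* ps = &fam->pslot[(size_t)v * n];
        const uint8_t* ms = &fam->mslot[(size_t)v * n];
        for (int s = 0; s < nS; ++s) {
            int cnt[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
            for (size_t w = 0; w < who.size(); ++w) {
                int i = who[w];
                int dp = (s >> ps[i]) & 1, dm = (s >> ms[i]) & 1;
                int cls;
                if (fam->founderNo[i] >= 0 && (dp ^ dm)) cls = 4;
                else cls = dp && dm ? 3 : (dp ? 1 : (dm ? 2 : 0));
                cnt[(fam->aff[i] == 2 ? 0 : 5) + cls]++;
            }
            int64_t key = __builtin_popcount((unsigned)s);
            for (int c = 0; c < 10; ++c) key = (key << 5) | cnt[c];
            tmp[s] = key;
        }
        std::sort(tmp.begin(), tmp.end());
        int base = fam->ckey.size();
        for (int s = 0; s < nS; ) {
            int s2 = s;
            while (s2 < nS && tmp[s2] == tmp[s]) ++s2;
            auto it = reg.find(tmp[s]);
            int id;
            if (it == reg.end()) {
                id = reg.size();
                reg.emplace(tmp[s], id);
                fam->keyPacked.push_back(tmp[s]);
            } else id = it->second;
            fam->ckey.push_back(id);
            fam->ccount.push_back((double)(s2 - s));
            s = s2;
        }
        fam->crowPtr[v + 1] = fam->ckey.size();
        (void)base;
    }
    fam->K = reg.size();
    // uniform-inheritance key weights (null hypothesis), normalized so that
    // sum_k W0[k] * prior-free count = sum over (v, s) / nV
    fam->W0.assign(fam->K, 0.0);
    const double inv = 1.0 / nV;
    for (int v = 0; v < nV; ++v)
        for (int j = fam->crowPtr[v]; j < fam->crowPtr[v + 1]; ++j)
            fam->W0[fam->ckey[j]] += fam->ccount[j] * inv;
    fam->nmod = 0;
    fam->Tmat.clear(); fam->L0.clear();
    return fam->K;
}

// [[Rcpp::export(name = ".lgKeys")]]
IntegerMatrix lgKeys(SEXP xp) {
    LGFamily* fam = getFam(xp);
    IntegerMatrix out(fam->K, 11);
    for (int k = 0; k < fam->K; ++k) {
        int64_t key = fam->keyPacked[k];
        for (int c = 9; c >= 0; --c) {
            out(k, c + 1) = (int)(key & 31);
            key >>= 5;
        }
        out(k, 0) = (int)key;
    }
    colnames(out) = CharacterVector::create(
        "d", "nA0", "nA1p", "nA1m", "nA2", "nAfh",
        "nU0", "nU1p", "nU1m", "nU2", "nUfh");
    return out;
}

// [[Rcpp::export(name = ".lgW0")]]
NumericVector lgW0(SEXP xp) {
    LGFamily* fam = getFam(xp);
    return NumericVector(fam->W0.begin(), fam->W0.end());
}

static double penPow(double f, int k) {
    if (k == 0) return 1.0;
    if (f <= 0.0) return 0.0;
    return std::pow(f, k);
}

// models: 5 x nmod matrix, rows q, f0, f1pat, f1mat, f2.
// Tabulates P(affection | v) per model and the no-linkage normalizer.
// [[Rcpp::export(name = ".lgSetModels")]]
void lgSetModels(SEXP xp, NumericMatrix models) {
    LGFamily* fam = getFam(xp);
    if (fam->K == 0) stop("call .lgSetAffection first");
    if (models.nrow() != 5) stop("models must have 5 rows");
    const int nmod = models.ncol(), nV = fam->nV, nslot = 2 * fam->f;
    fam->nmod = nmod;
    fam->Tmat.assign((size_t)nmod * nV, 0.0);
    fam->L0.assign(nmod, 0.0);
    std::vector<double> phi((size_t)nmod * fam->K);
    IntegerMatrix keys = lgKeys(xp);
    const int PMAX = 33;
    double pw[12][PMAX];
    for (int m = 0; m < nmod; ++m) {
        double q = models(0, m), f0 = models(1, m), f1p = models(2, m),
               f1m = models(3, m), f2 = models(4, m);
        double fh = 0.5 * (f1p + f1m);   // founder heterozygote
        const double par[12] = {q, 1.0 - q, f0, f1p, f1m, f2, fh,
                                1.0 - f0, 1.0 - f1p, 1.0 - f1m, 1.0 - f2,
                                1.0 - fh};
        for (int t = 0; t < 12; ++t) {
            pw[t][0] = 1.0;
            for (int e = 1; e < PMAX; ++e) pw[t][e] = pw[t][e - 1] * par[t];
        }
        for (int k = 0; k < fam->K; ++k) {
            int d = keys(k, 0);
            double val = pw[0][d] * pw[1][nslot - d];
            val *= pw[2][keys(k, 1)] * pw[7][keys(k, 6)];
            val *= pw[3][keys(k, 2)] * pw[8][keys(k, 7)];
            val *= pw[4][keys(k, 3)] * pw[9][keys(k, 8)];
            val *= pw[5][keys(k, 4)] * pw[10][keys(k, 9)];
            val *= pw[6][keys(k, 5)] * pw[11][keys(k, 10)];
            phi[(size_t)k * nmod + m] = val;    // key-major for the fill below
        }
    }
    const double inv = 1.0 / nV;
    for (int v = 0; v < nV; ++v) {
        double* row = &fam->Tmat[(size_t)v * nmod];
        for (int j = fam->crowPtr[v]; j < fam->crowPtr[v + 1]; ++j) {
            const double* pk = &phi[(size_t)fam->ckey[j] * nmod];
            double c = fam->ccount[j];
            for (int m = 0; m < nmod; ++m) row[m] += c * pk[m];
        }
    }
    for (int v = 0; v < nV; ++v) {
        const double* row = &fam->Tmat[(size_t)v * nmod];
        for (int m = 0; m < nmod; ++m) fam->L0[m] += row[m] * inv;
    }
}

// [[Rcpp::export(name = ".lgLik")]]
double lgLik(SEXP xp, IntegerMatrix geno, NumericVector freq,
             NumericVector theta) {
    LGFamily* fam = getFam(xp);
    HMMState st;
    runHMM(*fam, geno, freq, theta, st);
    return st.loglik10;
}

// [[Rcpp::export(name = ".lgPosterior")]]
NumericMatrix lgPosterior(SEXP xp, IntegerMatrix geno, NumericVector freq,
                          NumericVector theta, IntegerVector scanIdx,
                          NumericVector thetaL, NumericVector thetaR) {
    LGFamily* fam = getFam(xp);
    HMMState st;
    runHMM(*fam, geno, freq, theta, st);
    const int P = scanIdx.size(), nV = fam->nV;
    NumericMatrix out(P, nV);
    std::vector<double> post(nV);
    for (int p = 0; p < P; ++p) {
        posteriorAt(*fam, st, scanIdx[p], thetaL[p], thetaR[p], post.data());
        for (int v = 0; v < nV; ++v) out(p, v) = post[v];
    }
    return out;
}

// log10 LR per (scan position, model) against the preset model table.
// [[Rcpp::export(name = ".lgScanLOD")]]
NumericMatrix lgScanLOD(SEXP xp, IntegerMatrix geno, NumericVector freq,
                        NumericVector theta, IntegerVector scanIdx,
                        NumericVector thetaL, NumericVector thetaR) {
    LGFamily* fam = getFam(xp);
    if (fam->nmod == 0) stop("call .lgSetModels first");
    HMMState st;
    runHMM(*fam, geno, freq, theta, st);
    const int P = scanIdx.size(), nV = fam->nV, nmod = fam->nmod;
    NumericMatrix out(P, nmod);
    std::vector<double> post(nV);
    std::vector<double> acc(nmod);
    for (int p = 0; p < P; ++p) {
        posteriorAt(*fam, st, scanIdx[p], thetaL[p], thetaR[p], post.data());
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int v = 0; v < nV; ++v) {
            double pv = post[v];
            if (pv == 0.0) continue;
            const double* row = &fam->Tmat[(size_t)v * nmod];
            for (int m = 0; m < nmod; ++m) acc[m] += pv * row[m];
        }
        for (int m = 0; m < nmod; ++m) {
            double l0 = fam->L0[m];
            out(p, m) = (l0 > 0.0 && acc[m] > 0.0)
                ? std::log10(acc[m] / l0) : R_NegInf;
        }
    }
    return out;
}

// Posterior key weights per scan position: a LOD for any trait model is then
// log10( (W %*% phi) / (W0 %*% phi) ).
// [[Rcpp::export(name = ".lgScanWeights")]]
NumericMatrix lgScanWeights(SEXP xp, IntegerMatrix geno, NumericVector freq,
                            NumericVector theta, IntegerVector scanIdx,
                            NumericVector thetaL, NumericVector thetaR) {
    LGFamily* fam = getFam(xp);
    if (fam->K == 0) stop("call .lgSetAffection first");
    HMMState st;
    runHMM(*fam, geno, freq, theta, st);
    const int P = scanIdx.size(), nV = fam->nV;
    NumericMatrix out(P, fam->K);
    std::vector<double> post(nV);
    for (int p = 0; p < P; ++p) {
        posteriorAt(*fam, st, scanIdx[p], thetaL[p], thetaR[p], post.data());
        double* row = &out(p, 0);
        for (int v = 0; v < nV; ++v) {
            double pv = post[v];
            if (pv == 0.0) continue;
            for (int j = fam->crowPtr[v]; j < fam->crowPtr[v + 1]; ++j)
                out(p, fam->ckey[j]) += pv * fam->ccount[j];
        }
        (void)row;
    }
    return out;
}
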