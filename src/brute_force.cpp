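// Exhaustive pedigree likelihood by depth-first enumeration of every
// person's ordered multilocus haplotype pair.  Deliberately naive: founder
// haplotypes are enumerated against HWE + linkage-equilibrium priors,
// non-founder haplotypes against the per-meiosis transmission table obtained
// by summing over all inheritance patterns with Haldane-independent
// recombination between adjacent loci.  Serves as the test oracle for the
// inheritance-vector HMM; shares no code with it.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct BFProblem {
    int n, L, H;                      // persons, loci, 1 << L
    std::vector<int> father, mother;  // -1 founders
    std::vector<int> type;            // per locus: 0 marker, 1 trait
    std::vector<double> pbit;         // P(bit = 1) per locus
    std::vector<int> obs;             // n*L: marker genotype code / affection
    double f0, f1p, f1m, f2;
    std::vector<double> trans;        // H*H*H transmission table
    std::vector<std::vector<int>> candP;   // candidate (hp, hm) pairs packed
    std::vector<double> prior;        // founder prior per haplotype
};

double hapPrior(const BFProblem& pb, int h) {
    double pr = 1.0;
    for (int l = 0; l < pb.L; ++l)
        pr *= ((h >> l) & 1) ? pb.pbit[l] : 1.0 - pb.pbit[l];
    return pr;
}

// penetrance / observation factor for one person given ordered haplotypes
double personFactor(const BFProblem& pb, int i, int hp, int hm, bool* ok) {
    double fac = 1.0;
    *ok = true;
    for (int l = 0; l < pb.L; ++l) {
        int bp = (hp >> l) & 1, bm = (hm >> l) & 1;
        int o = pb.obs[(size_t)i * pb.L + l];
        if (pb.type[l] == 0) {
            if (o < 0) continue;
            if (bp + bm != o) { *ok = false; return 0.0; }
        } else {
            if (o == 0) continue;
            double pen;
            if (bp && bm) pen = pb.f2;
            else if (bp) pen = pb.f1p;
            else if (bm) pen = pb.f1m;
            else pen = pb.f0;
            fac *= (o == 2) ? pen : 1.0 - pen;
        }
    }
    return fac;
}

double dfs(const BFProblem& pb, int i, std::vector<int>& hpv,
           std::vector<int>& hmv) {
    if (i == pb.n) return 1.0;
    double total = 0.0;
    const int H = pb.H;
    for (size_t c = 0; c < pb.candP[i].size(); ++c) {
        int packed = pb.candP[i][c];
        int hp = packed / H, hm = packed % H;
        double fac;
        if (pb.father[i] < 0) {
            fac = hapPrior(pb, hp) * hapPrior(pb, hm);
        } else {
            int fa = pb.father[i], mo = pb.mother[i];
            fac = pb.trans[((size_t)hpv[fa] * H + hmv[fa]) * H + hp] *
                  pb.trans[((size_t)hpv[mo] * H + hmv[mo]) * H + hm];
        }
        if (fac == 0.0) continue;
        bool ok;
        fac *= personFactor(pb, i, hp, hm, &ok);
        if (!ok || fac == 0.0) continue;
        hpv[i] = hp; hmv[i] = hm;
        total += fac * dfs(pb, i + 1, hpv, hmv);
    }
    return total;
}

}  // namespace

// father/mother 1-based (0 = founder), persons topologically sorted.
// lociType: 0 marker / 1 trait; obs: n x L (markers: -1/0/1/2 count of
// allele 2; trait: affection 0/1/2); pbit: P(bit=1) per locus (markers:
// frequency of allele 2, trait: disease-allele frequency); pen: f0, f1pat,
// f1mat, f2; theta: L-1 recombination fractions.
// [[Rcpp::export(name = ".bfLikelihood")]]
double bfLikelihood(IntegerVector father, IntegerVector mother,
                    IntegerVector lociType, IntegerMatrix obs,
                    NumericVector pbit, NumericVector pen,
                    NumericVector theta) {
    BFProblem pb;
    pb.n = father.size();
    pb.L = lociType.size();
    if (pb.L > 5) stop("brute force limited to 5 loci");
    if (pb.n > 12) stop("brute force limited to 12 persons");
    pb.H = 1 << pb.L;
    pb.father.resize(pb.n); pb.mother.resize(pb.n);
    for (int i = 0; i < pb.n; ++i) {
        pb.father[i] = father[i] - 1;
        pb.mother[i] = mother[i] - 1;
        if (pb.father[i] >= i || pb.mother[i] >= i)
            stop("persons must be sorted with parents before children");
    }
    pb.type.assign(lociType.begin(), lociType.end());
    pb.pbit.assign(pbit.begin(), pbit.end());
    pb.f0 = pen[0]; pb.f1p = pen[1]; pb.f1m = pen[2]; pb.f2 = pen[3];
    pb.obs.resize((size_t)pb.n * pb.L);
    for (int i = 0; i < pb.n; ++i)
        for (int l = 0; l < pb.L; ++l) {
            int o = obs(i, l);
            pb.obs[(size_t)i * pb.L + l] = (o == NA_INTEGER) ? -1 : o;
        }
    const int H = pb.H;
    // transmission table: P(child hap h | parent ordered pair (a, b))
    pb.trans.assign((size_t)H * H * H, 0.0);
    for (int w = 0; w < H; ++w) {
        double pw = 0.5;
        for (int l = 1; l < pb.L; ++l) {
            bool flip = ((w >> l) & 1) != ((w >> (l - 1)) & 1);
            pw *= flip ? theta[l - 1] : 1.0 - theta[l - 1];
        }
        for (int a = 0; a < H; ++a)
            for (int b = 0; b < H; ++b) {
                int h = 0;
                for (int l = 0; l < pb.L; ++l) {
                    int src = ((w >> l) & 1) ? b : a;
                    h |= ((src >> l) & 1) << l;
                }
                pb.trans[((size_t)a * H + b) * H + h] += pw;
            }
    }
    // candidate states filtered by marker observations
    pb.candP.resize(pb.n);
    double work = 1.0;
    for (int i = 0; i < pb.n; ++i) {
        for (int hp = 0; hp < H; ++hp)
            for (int hm = 0; hm < H; ++hm) {
                bool ok = true;
                for (int l = 0; l < pb.L && ok; ++l) {
                    if (pb.type[l] != 0) continue;
                    int o = pb.obs[(size_t)i * pb.L + l];
                    if (o >= 0 && ((hp >> l) & 1) + ((hm >> l) & 1) != o)
                        ok = false;
                }
                if (ok) pb.candP[i].push_back(hp * H + hm);
            }
        work *= std::max<size_t>(pb.candP[i].size(), 1);
        if (work > 5e8) stop("instance too large for brute force");
    }
    std::vector<int> hpv(pb.n), hmv(pb.n);
    return dfs(pb, 0, hpv, hmv);
}
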