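# Arbitrary-precision brute-force posterior oracle (mpmath, 60 digits).
# Reads a JSON problem from stdin:
#   nl: per-library coverage; kalt: L x 3 alternate-base counts;
#   p_alt: per-change induction probabilities (alt order); ri, ci: 0-based
#   row/column library index per well; i_l: per-library individual counts;
#   i_well, t_het, t_hom: prior parameters.
# Writes the posterior of every configuration (null first, then wells x
# nonzero-prior alts x {het, hom}) as decimal strings.
import sys
import json
from mpmath import mp, mpf, binomial

mp.dps = 60
d = json.load(sys.stdin)
L = len(d["nl"])
W = len(d["ri"])
nl = d["nl"]
k = d["kalt"]
p_alt = [mpf(str(x)) for x in d["p_alt"]]
i_l = d["i_l"]
iw = d["i_well"]
t_z = {"het": mpf(str(d["t_het"])), "hom": mpf(str(d["t_hom"]))}


def pmf(kk, nn, p):
    if p == 0:
        return mpf(1) if kk == 0 else mpf(0)
    if p == 1:
        return mpf(1) if kk == nn else mpf(0)
    return binomial(nn, kk) * p ** kk * (1 - p) ** (nn - kk)


p0 = [(1 - p) ** iw for p in p_alt]
p1 = [iw * p * (1 - p) ** (iw - 1) for p in p_alt]
prior_null = (p0[0] * p0[1] * p0[2]) ** W


def lik(well, alt_i, z):
    val = mpf(1)
    for mi in range(3):
        if well is None:
            keep = list(range(L))
        else:
            excl = {d["ri"][well], d["ci"][well]}
            keep = [l for l in range(L) if l not in excl]
        tot_k = sum(k[l][mi] for l in keep)
        tot_n = sum(nl[l] for l in keep)
        e = mpf(tot_k) / tot_n if tot_n > 0 else mpf(0)
        for l in range(L):
            mf = mpf(0)
            if well is not None and mi == alt_i and \
                    l in (d["ri"][well], d["ci"][well]):
                mf = (1 if z == "het" else 2) / mpf(2 * i_l[l])
            r = (1 - mf) * e + mf
            val *= pmf(k[l][mi], nl[l], r)
    return val


nums = [prior_null * lik(None, None, None)]
for w in range(W):
    for mi in range(3):
        if p_alt[mi] == 0:
            continue
        for z in ("het", "hom"):
            prior = t_z[z] * p1[mi] * p0[mi] ** (W - 1)
            for mj in range(3):
                if mj != mi:
                    prior *= p0[mj] ** W
            nums.append(prior * lik(w, mi, z))

tot = sum(nums)
print(json.dumps([mp.nstr(x / tot, 25) for x in nums]))
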