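"""Independent run-length feature oracle (numpy).

Generates the deterministic fixture ROI used by the R test suite, computes
the 16 direction-averaged run-length features with an implementation
written independently of the package (itertools-based line scanning), and
writes them to tests/testthat/fixtures/glrlm_reference.csv.
"""
import numpy as np

NX, NY, NZ = 4, 4, 3
lab = np.zeros((NX, NY, NZ), dtype=int)
for i in range(NX):
    for j in range(NY):
        for k in range(NZ):
            if (i + j + k) % 7 == 0:
                lab[i, j, k] = 0          # outside ROI
            else:
                lab[i, j, k] = (i * 7 + j * 3 + k * 5) % 4 + 1

DIRS = [(1,0,0),(0,1,0),(0,0,1),(1,1,0),(1,-1,0),(1,0,1),(1,0,-1),
        (0,1,1),(0,1,-1),(1,1,1),(1,1,-1),(1,-1,1),(1,-1,-1)]
NLEV = 4
nvox = int((lab > 0).sum())

def line_starts(d):
    dx, dy, dz = d
    for x in range(NX):
        for y in range(NY):
            for z in range(NZ):
                px, py, pz = x - dx, y - dy, z - dz
                if not (0 <= px < NX and 0 <= py < NY and 0 <= pz < NZ):
                    yield (x, y, z)

def runs_along(d):
    dx, dy, dz = d
    P = np.zeros((NLEV, NX + NY + NZ))
    for (x, y, z) in line_starts(d):
        seq = []
        while 0 <= x < NX and 0 <= y < NY and 0 <= z < NZ:
            seq.append(lab[x, y, z])
            x, y, z = x + dx, y + dy, z + dz
        # run-length encode, dropping zeros (mask gaps break runs)
        i = 0
        while i < len(seq):
            j = i
            while j < len(seq) and seq[j] == seq[i]:
                j += 1
            if seq[i] > 0:
                P[seq[i] - 1, j - i - 1] += 1
            i = j
    return P

def features(P):
    Nr = P.sum()
    g = np.arange(1, NLEV + 1)[:, None].astype(float)
    l = np.arange(1, P.shape[1] + 1)[None, :].astype(float)
    rg = P.sum(1); rl = P.sum(0)
    p = P / Nr
    mug = (rg / Nr * g[:, 0]).sum()
    mul = (rl / Nr * l[0]).sum()
    pn0 = p[p > 0]
    return dict(
        sre=(P / l**2).sum() / Nr, lre=(P * l**2).sum() / Nr,
        gln=(rg**2).sum() / Nr, glnn=(rg**2).sum() / Nr**2,
        rln=(rl**2).sum() / Nr, rlnn=(rl**2).sum() / Nr**2,
        rp=Nr / nvox,
        glv=(rg / Nr * (g[:, 0] - mug)**2).sum(),
        rlv=(rl / Nr * (l[0] - mul)**2).sum(),
        re=-(pn0 * np.log2(pn0)).sum(),
        lglre=(P / g**2).sum() / Nr, hglre=(P * g**2).sum() / Nr,
        srlgle=(P / g**2 / l**2).sum() / Nr,
        srhgle=(P * g**2 / l**2).sum() / Nr,
        lrlgle=(P / g**2 * l**2).sum() / Nr,
        lrhgle=(P * g**2 * l**2).sum() / Nr)

names = ["sre","lre","gln","glnn","rln","rlnn","rp","glv","rlv","re",
         "lglre","hglre","srlgle","srhgle","lrlgle","lrhgle"]
acc = {n: 0.0 for n in names}
for d in DIRS:
    f = features(runs_along(d))
    for n in names:
        acc[n] += f[n] / len(DIRS)

with open("tests/testthat/fixtures/glrlm_reference.csv", "w") as fh:
    fh.write("feature,value\n")
    for n in names:
        fh.write(f"{n},{acc[n]:.15g}\n")
print("nvox", nvox)
print({n: round(acc[n], 6) for n in names})
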