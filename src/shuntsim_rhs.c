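/* Compiled RHS of the closed-loop lumped-parameter circulation with
 * optional atrial / ventricular septal-defect branches, in the deSolve
 * compiled-model calling convention.
 *
 * State (12): VLA VLV VRA VRV | pARSYS pVENSYS pARPUL pVENPUL |
 *             QARSYS QVENSYS QARPUL QVENPUL
 * Units: volumes mL, pressures mmHg, flows mL/s, time s.
 *
 * Parameter vector (51 doubles, fixed order; see as_param_vector() in R):
 *   [0]      THB
 *   [1..28]  chambers LA LV RA RV, each {EA EB V0 tC TC tR TR}
 *   [29..36] valves MV AV TV PV, each {Rmin Rmax}
 *   [37..48] compartments ARSYS VENSYS ARPUL VENPUL, each {R C L}
 *   [49,50]  RASD RVSD (<= 0 encodes a closed defect)
 */
#include <R.h>
#include <math.h>

static double parms[51];

#define THB     parms[0]
#define CH(i,j) parms[1 + 7*(i) + (j)]   /* j: 0 EA, 1 EB, 2 V0, 3 tC, 4 TC, 5 tR, 6 TR */
#define VRMIN(i) parms[29 + 2*(i)]
#define VRMAX(i) parms[30 + 2*(i)]
#define WR(i)   parms[37 + 3*(i)]
#define WC(i)   parms[38 + 3*(i)]
#define WL(i)   parms[39 + 3*(i)]
#define RASD    parms[49]
#define RVSD    parms[50]

void shunt_initmod(void (*odeparms)(int *, double *))
{
    int n = 51;
    odeparms(&n, parms);
}

/* Half-cosine activation: 0 -> 1 over [tC, tC+TC], 1 -> 0 over [tR, tR+TR],
 * both windows taken modulo THB (relaxation may wrap past the cycle end). */
static double activation_c(double t, int i)
{
    double tC = CH(i, 3), TC = CH(i, 4), tR = CH(i, 5), TR = CH(i, 6);
    double u = fmod(t - tC, THB);
    if (u < 0) u += THB;
    if (u < TC) return 0.5 * (1.0 - cos(M_PI * u / TC));
    double v = fmod(t - tR, THB);
    if (v < 0) v += THB;
    if (v < TR) return 0.5 * (1.0 + cos(M_PI * v / TR));
    return 0.0;
}

static double valve_c(double p_up, double p_down, int i)
{
    double dp = p_up - p_down;
    return dp / (dp > 0 ? VRMIN(i) : VRMAX(i));
}

void shunt_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double VLA = y[0], VLV = y[1], VRA = y[2], VRV = y[3];
    double pAS = y[4], pVS = y[5], pAP = y[6], pVP = y[7];
    double QAS = y[8], QVS = y[9], QAP = y[10], QVP = y[11];

    double pLA = (CH(0,1) + CH(0,0) * activation_c(*t, 0)) * (VLA - CH(0,2));
    double pLV = (CH(1,1) + CH(1,0) * activation_c(*t, 1)) * (VLV - CH(1,2));
    double pRA = (CH(2,1) + CH(2,0) * activation_c(*t, 2)) * (VRA - CH(2,2));
    double pRV = (CH(3,1) + CH(3,0) * activation_c(*t, 3)) * (VRV - CH(3,2));

    double QMV = valve_c(pLA, pLV, 0);
    double QAV = valve_c(pLV, pAS, 1);
    double QTV = valve_c(pRA, pRV, 2);
    double QPV = valve_c(pRV, pAP, 3);

    double QASDf = (RASD > 0) ? (pLA - pRA) / RASD : 0.0;
    double QVSDf = (RVSD > 0) ? (pLV - pRV) / RVSD : 0.0;

    ydot[0] = QVP - QMV - QASDf;            /* dVLA  */
    ydot[1] = QMV - QAV - QVSDf;            /* dVLV  */
    ydot[2] = QVS - QTV + QASDf;            /* dVRA  */
    ydot[3] = QTV - QPV + QVSDf;            /* dVRV  */
    ydot[4] = (QAV - QAS) / WC(0);          /* dpARSYS  */
    ydot[5] = (QAS - QVS) / WC(1);          /* dpVENSYS */
    ydot[6] = (QPV - QAP) / WC(2);          /* dpARPUL  */
    ydot[7] = (QAP - QVP) / WC(3);          /* dpVENPUL */
    ydot[8]  = (pAS - pVS - WR(0) * QAS) / WL(0);   /* dQARSYS  */
    ydot[9]  = (pVS - pRA - WR(1) * QVS) / WL(1);   /* dQVENSYS */
    ydot[10] = (pAP - pVP - WR(2) * QAP) / WL(2);   /* dQARPUL  */
    ydot[11] = (pVP - pLA - WR(3) * QVP) / WL(3);   /* dQVENPUL */

    if (ip[0] >= 10) {
        yout[0] = QMV; yout[1] = QAV; yout[2] = QTV; yout[3] = QPV;
        yout[4] = QASDf; yout[5] = QVSDf;
        yout[6] = pLA; yout[7] = pLV; yout[8] = pRA; yout[9] = pRV;
    }
}
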