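id,geometric,h_bond,connectivity,asa,integy_moment,volume_shape
A,0.520589072919,1.90808383464,-1.16989866994,-0.977149468323,1.21626648114,0.468847940136
C,-1.07969076235,1.73094452724,-0.206200160293,2.12449113551,-0.493843235614,-0.544147673198
D,0.139238115019,0.0581458372593,-0.930610309244,0.687698960562,-0.227784720977,-0.165414153808
E,-0.0847487849486,0.645328161775,0.449397565792,-0.34336822018,-1.11164888705,0.552166562573
F,-0.666639615285,1.72562898651,-0.644806454562,0.785169472674,0.99583308941,1.0333302116
G,-2.51608903201,-0.528966917456,-0.231422689811,-1.15557746077,0.561828890946,-0.0461788047835
H,-0.735146797457,0.166392025613,-1.23636801145,1.50891634639,-1.56427855652,2.6387073126
I,-1.02012226314,-0.254723574764,-0.960955298223,-1.15549616026,1.48107701911,0.589005749225
K,0.113554441297,0.332782359438,0.13395628157,-1.55681181021,-1.16920515011,-0.202377334229
L,-0.47379098184,0.182432812828,-0.999052722969,-0.0552479252236,-1.05201353747,0.441560138002
M,-0.408214704338,1.16459374952,-0.141470690813,0.849193162703,-1.47184552483,-0.100257702083
N,-0.730433278594,0.593492850728,0.167329899649,-0.0110967225037,-1.19343692076,-1.09340399199
P,-0.221436599406,-0.891779729217,-0.198788612672,-0.760313831781,-0.347979424692,0.503247338583
Q,-0.225816524429,0.577253310357,-0.291207188092,1.17579925168,0.532822543149,0.949240091118
R,-2.54688144613,-0.824905581058,-1.73439703425,2.41444970903,-0.710988575851,0.382802056022
S,1.3470014993,-1.15725385762,-0.272728331733,-1.95851276823,-0.198989137632,0.371578210898
T,0.61640814585,0.777998774006,-1.7999294817,1.47358989343,-0.281373323518,0.157216401651
V,0.217564338308,-1.20422178597,1.1527409768,-0.474883961499,1.1709262752,0.847939889975
W,-0.8047188304,0.306714102148,-1.00331948559,0.981170983786,2.28873318592,-1.28339265651
Y,0.689746777626,-0.833658540642,0.148210044293,-1.82435521954,-1.0688566145,1.15827860809
101,-0.32867201409,1.4181411635,0.519496680749,-0.260610817352,1.90620418856,-0.909106213166
102,-0.164681576926,0.711786117851,0.00543629447576,-0.958845312574,2.13179771848,0.334990705169
103,-1.39202887977,-0.402497722862,1.34702083465,-0.490295710067,0.231456363015,0.775854081916
104,1.4658247612,0.799362218715,-0.847033417296,-1.0772967136,0.896945737827,0.237140152276
105,0.0482068082254,0.426484435557,0.443398017316,0.369425910544,-1.73879271235,-1.55987013459
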