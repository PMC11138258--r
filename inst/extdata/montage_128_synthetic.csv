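label,x,y,z,excluded
E1,0.045208,0.116276,0.992188,FALSE
E2,-0.193018,-0.095235,0.976562,FALSE
E3,0.265735,-0.077357,0.960938,FALSE
E4,-0.169338,0.278763,0.945312,FALSE
E5,-0.071641,-0.361315,0.929688,FALSE
E6,0.326894,0.240063,0.914062,FALSE
E7,-0.436533,0.047419,0.898438,FALSE
E8,0.31007,-0.352843,0.882812,FALSE
E9,0.01029,0.497875,0.867188,FALSE
E10,-0.36204,-0.379168,0.851562,FALSE
E11,0.547598,0.036674,0.835938,FALSE
E12,-0.446585,0.35728,0.820312,FALSE
E13,0.091309,-0.586635,0.804688,FALSE
E14,0.340359,0.511406,0.789062,FALSE
E15,-0.61541,-0.151872,0.773438,FALSE
E16,0.572698,-0.31263,0.757812,FALSE
E17,-0.216845,0.634142,0.742188,FALSE
E18,-0.275235,-0.629565,0.726562,FALSE
E19,0.642985,0.284846,0.710938,FALSE
E20,-0.681174,0.229222,0.695312,FALSE
E21,0.354591,-0.642098,0.679688,FALSE
E22,0.175596,0.726765,0.664062,FALSE
E23,-0.631679,-0.424866,0.648438,FALSE
E24,0.765665,-0.115352,0.632812,FALSE
E25,-0.494521,0.611987,0.617188,FALSE
E26,-0.049491,-0.797291,0.601562,FALSE
E27,0.583356,0.56247,0.585938,FALSE
E28,-0.82116,-0.02098,0.570312,FALSE
E29,0.627689,-0.546194,0.554688,FALSE
E30,-0.095041,0.836886,0.539062,FALSE
E31,-0.500989,-0.689219,0.523438,FALSE
E32,0.84419,0.171669,0.507812,FALSE
E33,-0.746173,0.448305,0.492188,FALSE
E34,0.249838,-0.842893,0.476562,FALSE
E35,0.388776,0.79774,0.460938,FALSE
E36,-0.832926,-0.328529,0.445312,FALSE
E37,0.843191,-0.323107,0.429688,FALSE
E38,-0.406736,0.814321,0.414062,FALSE
E39,-0.252061,-0.88188,0.398438,FALSE
E40,0.787213,0.483477,0.382812,FALSE
E41,-0.913257,0.176453,0.367188,FALSE
E42,0.5578,-0.75184,0.351562,FALSE
E43,0.097146,0.936861,0.335938,FALSE
E44,-0.708533,-0.628794,0.320312,FALSE
E45,0.952334,-0.015035,0.304688,FALSE
E46,-0.695595,0.657716,0.289062,FALSE
E47,0.068957,-0.959415,0.273438,FALSE
E48,0.599901,0.757397,0.257812,FALSE
E49,-0.957947,-0.153894,0.242188,FALSE
E50,0.81346,-0.535679,0.226562,FALSE
E51,-0.23883,0.947874,0.210938,FALSE
E52,-0.465713,-0.863113,0.195312,FALSE
E53,0.929245,0.322827,0.179688,FALSE
E54,-0.905765,0.390733,0.164062,FALSE
E55,0.404959,-0.902205,0.148438,FALSE
E56,0.311524,0.940911,0.132812,FALSE
E57,-0.867003,-0.484327,0.117188,FALSE
E58,0.968132,-0.22892,0.101562,FALSE
E59,-0.560064,0.82398,0.085938,FALSE
E60,-0.143793,-0.987107,0.070312,FALSE
E61,0.773567,0.63135,0.054688,FALSE
E62,-0.997607,0.057041,0.039062,FALSE
E63,0.697414,-0.716285,0.023438,FALSE
E64,-0.030416,0.999507,0.007812,FALSE
E65,-0.65273,-0.757551,-0.007812,FALSE
E66,0.992778,0.117653,-0.023438,FALSE
E67,-0.811121,0.583573,-0.039062,FALSE
E68,0.203748,-0.977495,-0.054688,FALSE
E69,0.509551,0.857563,-0.070312,FALSE
E70,-0.95383,-0.287789,-0.085938,FALSE
E71,0.896398,-0.431458,-0.101562,FALSE
E72,-0.368892,0.922055,-0.117188,FALSE
E73,-0.350135,-0.927236,-0.132812,FALSE
E74,0.882537,0.446201,-0.148438,FALSE
E75,-0.94978,0.266463,-0.164062,FALSE
E76,0.518907,-0.835732,-0.179688,FALSE
E77,0.181352,0.963828,-0.195312,FALSE
E78,-0.782186,-0.586252,-0.210938,FALSE
E79,0.969281,-0.095731,-0.226562,FALSE
E80,-0.647538,0.722523,-0.242188,FALSE
E81,-0.010539,-0.966137,-0.257812,FALSE
E82,0.657445,0.702138,-0.273438,FALSE
E83,-0.954501,-0.073286,-0.289062,FALSE
E84,0.749501,-0.58772,-0.304688,FALSE
E85,-0.15482,0.934575,-0.320312,FALSE
E86,-0.514174,-0.789158,-0.335938,FALSE
E87,0.906665,0.233156,-0.351562,FALSE
E88,-0.820732,0.43769,-0.367188,FALSE
E89,0.307424,-0.871175,-0.382812,FALSE
E90,0.359189,0.843938,-0.398438,FALSE
E91,-0.828603,-0.376789,-0.414062,FALSE
E92,0.85859,-0.279629,-0.429688,FALSE
E93,-0.440471,0.77954,-0.445312,FALSE
E94,-0.199992,-0.864604,-0.460938,FALSE
E95,0.724664,0.497745,-0.476562,FALSE
E96,-0.862,0.121277,-0.492188,FALSE
E97,0.547952,-0.664737,-0.507812,FALSE
E98,0.04449,0.850902,-0.523438,FALSE
E99,-0.600594,-0.590507,-0.539062,FALSE
E100,0.83154,0.029365,-0.554688,FALSE
E101,-0.624901,0.533144,-0.570312,FALSE
E102,0.099292,-0.80425,-0.585938,FALSE
E103,0.46336,0.650707,-0.601562,FALSE
E104,-0.769469,-0.164308,-0.617188,FALSE
E105,0.667584,-0.392275,-0.632812,FALSE
E106,-0.223451,0.727735,-0.648438,FALSE
E107,-0.320978,-0.675274,-0.664062,FALSE
E108,0.679684,0.275779,-0.679688,FALSE
E109,-0.673598,0.250611,-0.695312,TRUE
E110,0.320366,-0.626046,-0.710938,TRUE
E111,0.182372,0.662456,-0.726562,TRUE
E112,-0.567637,-0.356295,-0.742188,TRUE
E113,0.641801,-0.117521,-0.757812,TRUE
E114,-0.382632,0.505358,-0.773438,TRUE
E115,-0.057396,-0.611626,-0.789062,TRUE
E116,0.440185,0.398391,-0.804688,TRUE
E117,-0.571905,0.003449,-0.820312,TRUE
E118,0.402443,-0.373159,-0.835938,TRUE
E119,-0.042683,0.522513,-0.851562,TRUE
E120,-0.305369,-0.393365,-0.867188,TRUE
E121,0.46303,0.079027,-0.882812,TRUE
E122,-0.369066,0.237908,-0.898438,TRUE
E123,0.102925,-0.392296,-0.914062,TRUE
E124,0.171743,0.325861,-0.929688,TRUE
E125,-0.307044,-0.110038,-0.945312,TRUE
E126,0.255186,-0.107142,-0.960938,TRUE
E127,-0.090049,0.195491,-0.976562,TRUE
E128,-0.038054,-0.11881,-0.992188,TRUE
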