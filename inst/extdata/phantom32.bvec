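0.000000000000000000 0.999877922236009797 -0.736558334944455995 0.087158514223632300 0.604788567343508610 -0.974928320478466559 0.831199175366711951 -0.254192285831327969 -0.448069042308008481 0.905577520274875258 -0.882672684062636548 0.400379470143040483 0.279289676927065966 -0.796470088380677677 0.885507001526951831 -0.512697397949270273 -0.112428923756007174 0.655162244964144658 -0.836499334517517013 0.578368093087481605 -0.036624373131522996 -0.491971014737171197 0.734049986453738201 -0.583684672426503570 0.148971653084174704 0.319830068871488071 -0.575563831479870225 0.508856394172394921 -0.197410743957793511 -0.153907284120093940 0.342999752711611650 -0.292582713006165451 0.095233308959486937
0.000000000000000000 0.000000000000000000 0.674747770354857002 -0.993126315114713387 0.788839589641383676 -0.172451092498819458 -0.528740877221251182 0.945582633194394284 -0.862729675333000379 0.330715457981340943 0.364354452675771712 -0.855587671874120881 0.890419499863393193 -0.461570696307592176 -0.194676230243311627 0.729259290315212638 -0.867606245066312343 0.552171433658553368 0.034591873709749928 -0.575553501660228117 0.792035835469407923 -0.589545698002689189 0.098765387470847718 0.406112592207339917 -0.662193933793090772 0.558146115654905572 -0.183620560578633490 -0.235104560748761904 0.471702880577414385 -0.427901457428899956 0.180271057063448953 0.077123864172847306 -0.148109676387557149
0.000000000000000000 0.015625000000000000 0.046875000000000007 0.078125000000000000 0.109375000000000014 0.140625000000000000 0.171875000000000028 0.203125000000000000 0.234375000000000028 0.265625000000000000 0.296875000000000000 0.328125000000000056 0.359375000000000056 0.390625000000000000 0.421875000000000000 0.453125000000000000 0.484375000000000000 0.515625000000000000 0.546875000000000000 0.578125000000000000 0.609375000000000000 0.640625000000000000 0.671875000000000000 0.703125000000000000 0.734375000000000000 0.765625000000000111 0.796875000000000111 0.828125000000000000 0.859375000000000000 0.890625000000000000 0.921875000000000000 0.953125000000000000 0.984375000000000000
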