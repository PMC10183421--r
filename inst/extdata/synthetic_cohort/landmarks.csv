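subject_id,point_id,x,y
S001,1,26.259370781188473,-15.462521233179913
S001,4,-23.29630895445478,-17.881988362376905
S001,7,14.641338610636552,-0.06112786725116137
S001,8,-14.31679529106321,0.3816606306640353
S001,9,-0.5811939325391391,12.704019674881659
S002,1,-25.424332059384476,-16.867849182939782
S002,4,20.73121665671709,-15.479440211034737
S002,7,-11.955894555974021,-0.16117980345668131
S002,8,11.97880668462155,0.20758311958347087
S002,9,-2.9059401710063932,13.389195043999642
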