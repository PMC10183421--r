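[{"subject_id":"S001","side":"right","pixel_spacing_mm":1,"fibula_contour":[[14.7389264229869,0],[13.6406602966039,0.910723555301113],[12.5423941702209,1.82144711060223],[11.4441280438379,2.73217066590334],[10.345861917455,3.64289422120445],[9.24759579107196,4.55361777650556],[8.14932966468896,5.46434133180668],[7.05106353830596,6.37506488710779],[5.95279741192296,7.2857884424089],[4.85453128553997,8.19651199771002],[3.75626515915697,9.10723555301113],[2.65799903277397,10.0179591083122],[1.55973290639098,10.9286826636134],[0.46146678000798,11.8394062189145],[-0.63679934637502,12.7501297742156],[-1.72157835226824,11.7693505608144],[-2.80635735816147,10.7885713474132],[-3.89113636405469,9.80779213401199],[-4.97591536994792,8.82701292061079],[-6.06069437584114,7.84623370720959],[-7.14547338173437,6.86545449380839],[-8.23025238762759,5.88467528040719],[-9.31503139352082,4.90389606700599],[-10.399810399414,3.92311685360479],[-11.4845894053073,2.9423376402036],[-12.5693684112005,1.9615584268024],[-13.6541474170937,0.980779213401197],[-14.7389264229869,0],[-13.6808433224799,-0.662770911148847],[-12.5930146380832,-1.2754975073133],[-11.4778055821325,-1.83684756723056],[-10.337640898757,-2.34560057511037],[-9.17499959187749,-2.80065037434249],[-7.99240953523054,-3.20100757255847],[-6.79244197613675,-3.54580169281879],[-5.57770594496456,-3.834283066248],[-4.3508425824439,-4.06582446200282],[-3.11451939716404,-4.23992245102928],[-1.871424465741,-4.35619850064371],[-0.624260588264947,-4.41439979755773],[0.62426058826495,-4.41439979755773],[1.87142446574101,-4.35619850064371],[3.11451939716404,-4.23992245102928],[4.3508425824439,-4.06582446200282],[5.57770594496457,-3.834283066248],[6.79244197613676,-3.54580169281879],[7.99240953523054,-3.20100757255846],[9.1749995918775,-2.80065037434249],[10.337640898757,-2.34560057511037],[11.4778055821325,-1.83684756723056],[12.5930146380832,-1.2754975073133],[13.6808433224799,-0.662770911148844]],"height_from_plafond_mm":15.4824630732656,"height_from_fibular_tip_mm":45.5494065214123,"tibia_contour":[[31.9522444115577,-25.7050576569137],[29.2906756167869,-25.7050576569137],[26.629106822016,-25.7050576569137],[23.9675380272452,-25.7050576569137],[21.3059692324744,-25.7050576569137],[18.6444004377035,-25.7050576569137],[15.9828316429327,-25.7050576569137],[13.3212628481619,-25.7050576569137],[10.659694053391,-25.7050576569137],[7.99812525862022,-25.7050576569137],[5.33655646384938,-25.7050576569137],[2.67498766907855,-25.7050576569137],[0.013418874307721,-25.7050576569137],[-2.64814992046311,-25.7050576569137],[-5.30971871523395,-25.7050576569137],[-7.97128751000477,-25.7050576569137],[-10.6328563047756,-25.7050576569137],[-13.2944250995464,-25.7050576569137],[-15.9559938943173,-25.7050576569137],[-18.6175626890881,-25.7050576569137],[-21.2791314838589,-25.7050576569137],[-23.9407002786298,-25.7050576569137],[-26.6022690734006,-25.7050576569137],[-29.2638378681714,-25.7050576569137],[-29.2638378681714,-3.79739085957001],[-26.6022690734006,-3.86981400723709],[-23.9407002786298,-3.98396774342448],[-21.2791314838589,-4.15300201617518],[-18.6175626890881,-4.38758761436202],[-15.9559938943173,-4.69169411247261],[-13.2944250995464,-5.05815921084421],[-10.6328563047756,-5.465579515112],[-7.97128751000477,-5.87821036061727],[-5.30971871523395,-6.24999363686775],[-2.64814992046311,-6.53254893054308],[0.013418874307721,-6.685381649345],[2.67498766907855,-6.685381649345],[5.33655646384938,-6.53254893054308],[7.99812525862022,-6.24999363686775],[10.659694053391,-5.87821036061727],[13.3212628481619,-5.465579515112],[15.9828316429327,-5.05815921084421],[18.6444004377035,-4.69169411247261],[21.3059692324744,-4.38758761436202],[23.9675380272452,-4.15300201617518],[26.629106822016,-3.98396774342448],[29.2906756167869,-3.86981400723709],[31.9522444115577,-3.79739085957001]]},{"subject_id":"S002","side":"left","pixel_spacing_mm":1,"fibula_contour":[[-12.2132106561706,0],[-11.381648110482,1.23008733183799],[-10.5500855647934,2.46017466367599],[-9.71852301910481,3.69026199551398],[-8.88696047341621,4.92034932735197],[-8.05539792772762,6.15043665918997],[-7.22383538203902,7.38052399102796],[-6.39227283635042,8.61061132286595],[-5.56071029066183,9.84069865470395],[-4.72914774497323,11.0707859865419],[-3.89758519928463,12.3008733183799],[-3.06602265359604,13.5309606502179],[-1.97464884575556,12.5644634609166],[-0.883275037915088,11.5979662716154],[0.208098769925386,10.6314690823141],[1.29947257776586,9.6649718930128],[2.39084638560633,8.69847470371153],[3.48222019344681,7.73197751441024],[4.57359400128728,6.76548032510896],[5.66496780912776,5.79898313580768],[6.75634161696823,4.8324859465064],[7.8477154248087,3.86598875720512],[8.93908923264918,2.89949156790384],[10.0304630404897,1.93299437860256],[11.1218368483301,0.966497189301281],[12.2132106561706,0],[11.3364445045958,-0.549196089480343],[10.4350300800254,-1.05692363888474],[9.51092728345044,-1.52207872120682],[8.56614534607176,-1.94364997265875],[7.60273846072775,-2.32072079162981],[6.62280131556389,-2.65247133160809],[5.62846453965554,-2.93818028373236],[4.62189007048602,-3.17722644509847],[3.60526645335244,-3.36909006941014],[2.58080408291945,-3.51335399703784],[1.55073039726692,-3.60970456202835],[0.517285034881106,-3.65793227409323],[-0.517285034881094,-3.65793227409323],[-1.55073039726691,-3.60970456202835],[-2.58080408291944,-3.51335399703784],[-3.60526645335244,-3.36909006941014],[-4.62189007048601,-3.17722644509847],[-5.62846453965553,-2.93818028373237],[-6.62280131556388,-2.65247133160809],[-7.60273846072774,-2.32072079162981],[-8.56614534607175,-1.94364997265875],[-9.51092728345044,-1.52207872120682],[-10.4350300800254,-1.05692363888475],[-11.3364445045958,-0.549196089480347]],"height_from_plafond_mm":15.9014727299449,"height_from_fibular_tip_mm":42.8827890955949,"tibia_contour":[[-31.447872089776,-25.7786942444613],[-28.9256785687496,-25.7786942444613],[-26.4034850477232,-25.7786942444613],[-23.8812915266967,-25.7786942444613],[-21.3590980056703,-25.7786942444613],[-18.8369044846439,-25.7786942444613],[-16.3147109636175,-25.7786942444613],[-13.7925174425911,-25.7786942444613],[-11.2703239215647,-25.7786942444613],[-8.74813040053827,-25.7786942444613],[-6.22593687951185,-25.7786942444613],[-3.70374335848544,-25.7786942444613],[-1.18154983745903,-25.7786942444613],[1.34064368356738,-25.7786942444613],[3.8628372045938,-25.7786942444613],[6.38503072562021,-25.7786942444613],[8.90722424664662,-25.7786942444613],[11.429417767673,-25.7786942444613],[13.9516112886994,-25.7786942444613],[16.4738048097259,-25.7786942444613],[18.9959983307523,-25.7786942444613],[21.5181918517787,-25.7786942444613],[24.0403853728051,-25.7786942444613],[26.5625788938315,-25.7786942444613],[26.5625788938315,-3.8625981053918],[24.0403853728051,-3.93081288508792],[21.5181918517787,-4.03996570443616],[18.9959983307523,-4.203813282929],[16.4738048097259,-4.43399125065792],[13.9516112886994,-4.7356125426835],[11.429417767673,-5.10248877086093],[8.90722424664662,-5.51359784844323],[6.38503072562021,-5.93266183145294],[3.8628372045938,-6.31214241926319],[1.34064368356738,-6.60158409255239],[-1.18154983745903,-6.75847894185839],[-3.70374335848544,-6.75847894185839],[-6.22593687951185,-6.60158409255239],[-8.74813040053827,-6.31214241926319],[-11.2703239215647,-5.93266183145294],[-13.7925174425911,-5.51359784844323],[-16.3147109636175,-5.10248877086093],[-18.8369044846439,-4.7356125426835],[-21.3590980056703,-4.43399125065792],[-23.8812915266967,-4.203813282929],[-26.4034850477232,-4.03996570443616],[-28.9256785687496,-3.93081288508792],[-31.447872089776,-3.8625981053918]]}]
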