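(((((t18:7.93639530580421,(t3:7.59515120922009,((t19:3.76259179606818,(t56:2.26769602525704,t79:2.26769602525704):1.49489577081114):0.878462217792979,(t47:2.77807696901689,(t97:1.08522255366792,(t72:0.183352379400546,t117:0.183352379400546):0.901870174267377):1.69285441534897):1.86297704484427):2.95409719535893):0.341244096584118):6.43793918515684,(t5:5.23949700487294,((t75:1.87428242814346,t84:1.87428242814346):0.622087349793463,(t38:0.0561656251199368,t120:0.0561656251199368):2.44020415281699):2.74312722693601):9.13483748608811):0.32588722830648,((t4:11.7011216592637,(((t35:5.62991224963019,(t33:3.43296881708253,(t67:2.664598569188,(t113:0.348694824175031,(t74:0.0362077695154274,t121:0.0362077695154274):0.312487054659604):2.31590374501297):0.768370247894534):2.19694343254766):0.138023725101298,(t44:4.7301083598119,(t9:3.62739210002302,(t64:3.02878244858208,t69:3.02878244858208):0.598609651440934):1.10271625978889):1.03782761491958):1.34288398546021,(t39:5.15877062435461,(t24:2.36191363962593,(t77:2.24975862438263,t80:2.24975862438263):0.112155015243305):2.79685698472867):1.95204933583709):4.59030169907199):1.29591370624868,(((t13:7.5434038538129,(t21:2.38813162380439,t76:2.38813162380439):5.15527223000851):2.51466937424657,(((t41:4.90618929251138,(t61:3.73233168162548,((t6:1.09714930810338,t95:1.09714930810338):1.75388869725897,(t70:0.633805465591351,t108:0.633805465591351):2.217232539771):0.881293676263128):1.1738576108859):2.18138682092033,(t25:4.79148262621589,(t42:1.09103125973575,t96:1.09103125973575):3.70045136648014):2.29609348721582):0.369615861631155,(t22:4.67770222109104,t46:4.67770222109104):2.77948975397182):2.60088125299662):0.221487741803586,((t52:4.24108187552021,(t63:3.63064440419377,(t10:0.921488013900671,t100:0.921488013900671):2.7091563902931):0.610437471326441):1.73410690631506,(t98:0.939644883350979,(t30:0.0604518474658186,t119:0.0604518474658186):0.879193035885161):5.03554389848429):4.30437218802779):2.7174743956493):1.70318635375517):0.49673856735225,((((t8:8.20489389100432,((t17:6.62344796435272,((t28:3.82911850476234,(t55:2.27807044003572,(t78:0.213789719425595,t116:0.213789719425595):2.06428072061013):1.55104806472662):0.6456840619243,(t51:1.49128701814342,(t87:1.16983547056648,t93:1.16983547056648):0.321451547576943):2.98351554854322):2.14864539766608):0.968925321323546,((((t54:3.73585678323333,t60:3.73585678323333):0.250443807563477,(t68:3.13540565474845,(t20:1.2404128932496,(t88:0.855843097316297,t102:0.855843097316297):0.384569795933306):1.89499276149885):0.850894936048355):0.646703319351367,(t86:1.84621427077343,(t48:0.882950029633166,(t101:0.268632201210445,t114:0.268632201210445):0.614317828422721):0.963264241140262):2.78678963937474):1.21656926827514,(t57:3.7622455329077,(t31:2.04743269452379,t82:2.04743269452379):1.71481283838391):2.08732764551562):1.74280010725295):0.612520605328052):1.88531391298845,(t12:3.49449208238064,t66:3.49449208238064):6.59571572161213):0.0545138880359469,((t27:6.65606872926931,(t11:1.21417249218658,t89:1.21417249218658):5.44189623708273):1.82353772593496,((t16:3.99618478595248,(t53:2.79819208920108,t71:2.79819208920108):1.1979926967514):0.770676826880955,(t43:2.00469649497886,t83:2.00469649497886):2.76216511785457):3.71274484237083):1.66511523682445):1.5948848848331,((((t34:1.20075718239853,((t92:0.720074758017669,t106:0.720074758017669):0.130899327957155,(t103:0.267014828108979,t115:0.267014828108979):0.583959257865845):0.349783096423706):4.54170986265507,(t26:0.59424703614591,t110:0.59424703614591):5.14822000890769):1.32593573229877,(t2:2.0525099130554,(t81:0.538893971860446,t111:0.538893971860446):1.51361594119496):5.01589286429697):0.116481891802444,((t23:5.2742321196799,(((t37:1.20798863927624,t90:1.20798863927624):3.51967634200294,(t45:0.936424801906534,(t99:0.806466965205819,t104:0.806466965205819):0.129957836700715):3.79124017937265):0.249443341095208,(t40:1.2015826287563,(t91:0.622285636586976,t109:0.622285636586976):0.579296992169327):3.77552569361809):0.297123797305512):0.932263344225428,(t59:3.74006640983631,(t29:3.67267869456956,(t62:0.0114402090411017,t122:0.0114402090411017):3.66123848552845):0.0673877152667538):2.46642905406902):0.978389205249487):4.554721907707):3.45735370975796):1.00303971338022,(((((t73:2.71089958031131,(t14:0.163156213518954,t118:0.163156213518954):2.54774336679236):1.8598178066158,(t50:0.743602907111808,t105:0.743602907111808):3.8271144798153):4.21627869311355,(t58:3.74674340975131,(t15:3.58497743414823,(t65:0.459901448635945,t112:0.459901448635945):3.12507598551228):0.161765975603087):5.04025267028935):0.225516271603702,((t85:1.10251541912457,t94:1.10251541912457):0.743950738307043,(t1:0.69496447208575,t107:0.69496447208575):1.15150168534586):7.16604619421275):2.89355782889366,(t32:5.81535075917106,(t36:5.3646361205542,(t7:4.60062252890783,t49:4.60062252890783):0.764013591646377):0.450714638616852):6.09071942136697):4.29392981946197);
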